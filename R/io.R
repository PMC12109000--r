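#' Construct a 3-channel waveform segment
#'
#' The central record of the pipeline: one contiguous multi-second window of
#' synchronized ECG, PPG and ABP samples from one subject, with its start
#' time (seconds from the subject's recording start), sampling rate,
#' demographics and optional ground-truth annotations. Sample indexing is
#' 1-based in R; time windows are half-open `[start, end)`.
#'
#' @param subject_id Opaque subject identifier.
#' @param t0 Segment start, seconds since subject recording start.
#' @param fs Sampling rate, Hz.
#' @param ecg,ppg,abp Numeric sample series of equal length (ECG and PPG in
#'   arbitrary units, ABP in mm Hg).
#' @param annotations Optional list of ground-truth landmarks (see
#'   [render_segment()]).
#' @param age,sex Demographics (years; 0 = male, 1 = female).
#' @return An object of class `waveform_segment`.
#' @export
waveform_segment <- function(subject_id, t0, fs, ecg, ppg, abp,
                             annotations = NULL, age = NA, sex = NA) {
  if (fs <= 0) stop("fs must be positive")
  nlen <- length(ecg)
  if (length(ppg) != nlen || length(abp) != nlen) {
    stop(
      "channel length mismatch for subject ", subject_id, " at t0=", t0,
      ": ecg=", nlen, " ppg=", length(ppg), " abp=", length(abp)
    )
  }
  structure(
    list(
      subject_id = as.character(subject_id), t0 = as.numeric(t0),
      fs = as.numeric(fs), ecg = as.numeric(ecg), ppg = as.numeric(ppg),
      abp = as.numeric(abp), annotations = annotations,
      age = age, sex = sex
    ),
    class = "waveform_segment"
  )
}

#' @export
print.waveform_segment <- function(x, ...) {
  cat(sprintf(
    "<waveform_segment> subject %s, t0=%.1f s, %d samples @ %g Hz\n",
    x$subject_id, x$t0, length(x$ecg), x$fs
  ))
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

seg_meta <- function(seg) {
  list(
    subject_id = seg$subject_id, t0 = seg$t0, fs = seg$fs,
    age = seg$age, sex = seg$sex, annotations = seg$annotations
  )
}

#' Save a segment dataset
#'
#' Two on-disk dialects are supported. `"csv"` writes one directory per
#' subject with one `segment_<k>.csv` (columns `ecg,ppg,abp`, full
#' double precision) plus a JSON sidecar carrying metadata and annotations —
#' chosen as the primary dialect for diffability. `"hdf5"` writes one group
#' per subject with `ecg`/`ppg`/`abp` sample matrices (samples x segments),
#' a `t0` vector, `age`/`sex` attributes and annotations as JSON strings;
#' it requires the `rhdf5` package.
#'
#' @param dataset A dataset as returned by [make_dataset()] or
#'   [load_dataset()].
#' @param path Target directory (csv) or `.h5` file (hdf5).
#' @param dialect `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (subj in dataset) {
      sdir <- file.path(path, paste0("subject_", subj$subject_id))
      dir.create(sdir, showWarnings = FALSE)
      for (k in seq_along(subj$segments)) {
        seg <- subj$segments[[k]]
        df <- data.frame(
          ecg = fmt_num(seg$ecg), ppg = fmt_num(seg$ppg),
          abp = fmt_num(seg$abp)
        )
        write.csv(df, file.path(sdir, sprintf("segment_%04d.csv", k)),
                  row.names = FALSE, quote = FALSE)
        write_json(seg_meta(seg),
                   file.path(sdir, sprintf("segment_%04d.json", k)),
                   auto_unbox = TRUE, digits = NA, null = "null")
      }
    }
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("the hdf5 dialect requires the rhdf5 package")
    }
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    for (subj in dataset) {
      grp <- paste0("/", subj$subject_id)
      rhdf5::h5createGroup(path, grp)
      segs <- subj$segments
      for (ch in c("ecg", "ppg", "abp")) {
        m <- vapply(segs, `[[`, numeric(length(segs[[1]][[ch]])), ch)
        rhdf5::h5write(m, path, paste0(grp, "/", ch))
      }
      rhdf5::h5write(vapply(segs, `[[`, numeric(1), "t0"), path,
                     paste0(grp, "/t0"))
      rhdf5::h5write(
        vapply(segs, function(s) {
          as.character(toJSON(seg_meta(s), auto_unbox = TRUE, digits = NA,
                              null = "null"))
        }, character(1)),
        path, paste0(grp, "/meta")
      )
      fid <- rhdf5::H5Fopen(path)
      gid <- rhdf5::H5Gopen(fid, grp)
      rhdf5::h5writeAttribute(subj$age, gid, "age")
      rhdf5::h5writeAttribute(subj$sex, gid, "sex")
      rhdf5::h5writeAttribute(segs[[1]]$fs, gid, "fs")
      rhdf5::H5Gclose(gid)
      rhdf5::H5Fclose(fid)
    }
    rhdf5::h5closeAll()
  }
  invisible(path)
}

meta_to_segment <- function(meta, ecg, ppg, abp) {
  ann <- meta$annotations
  if (!is.null(ann)) ann <- lapply(ann, unlist)
  waveform_segment(
    subject_id = meta$subject_id, t0 = meta$t0, fs = meta$fs,
    ecg = ecg, ppg = ppg, abp = abp, annotations = ann,
    age = meta$age %||% NA, sex = meta$sex %||% NA
  )
}

#' Load a segment dataset
#'
#' Inverse of [save_dataset()]; numeric series round-trip losslessly in both
#' dialects. Segments are ordered by `t0` within subject. Malformed files
#' raise an error naming the offending subject and segment.
#'
#' @inheritParams save_dataset
#' @return A dataset list grouped by subject.
#' @export
load_dataset <- function(path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  out <- list()
  if (dialect == "csv") {
    sdirs <- sort(list.dirs(path, recursive = FALSE))
    sdirs <- sdirs[grepl("subject_", basename(sdirs))]
    if (!length(sdirs)) {
      warning("no subjects found under ", path)
      return(out)
    }
    for (sdir in sdirs) {
      files <- sort(list.files(sdir, pattern = "^segment_\\d+\\.csv$",
                               full.names = TRUE))
      segs <- lapply(files, function(f) {
        meta_file <- sub("\\.csv$", ".json", f)
        if (!file.exists(meta_file)) {
          stop("missing sidecar for ", f)
        }
        meta <- read_json(meta_file, simplifyVector = FALSE)
        df <- tryCatch(
          read.csv(f, colClasses = "numeric"),
          error = function(e) stop("malformed segment file ", f, ": ",
                                   conditionMessage(e))
        )
        if (!all(c("ecg", "ppg", "abp") %in% names(df))) {
          stop("malformed segment file ", f, ": missing channel columns")
        }
        meta_to_segment(meta, df$ecg, df$ppg, df$abp)
      })
      segs <- segs[order(vapply(segs, `[[`, numeric(1), "t0"))]
      sid <- segs[[1]]$subject_id
      out[[sid]] <- list(
        subject_id = sid, age = segs[[1]]$age, sex = segs[[1]]$sex,
        segments = segs
      )
    }
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("the hdf5 dialect requires the rhdf5 package")
    }
    ls <- rhdf5::h5ls(path, recursive = FALSE)
    subjects <- ls$name[ls$otype == "H5I_GROUP"]
    if (!length(subjects)) {
      warning("no subjects found in ", path)
      return(out)
    }
    for (sid in sort(subjects)) {
      grp <- paste0("/", sid)
      ecg <- as.matrix(rhdf5::h5read(path, paste0(grp, "/ecg")))
      ppg <- as.matrix(rhdf5::h5read(path, paste0(grp, "/ppg")))
      abp <- as.matrix(rhdf5::h5read(path, paste0(grp, "/abp")))
      metas <- rhdf5::h5read(path, paste0(grp, "/meta"))
      if (!all(dim(ppg) == dim(ecg)) || !all(dim(abp) == dim(ecg))) {
        stop("channel shape mismatch for subject ", sid, " in ", path)
      }
      segs <- lapply(seq_len(ncol(ecg)), function(k) {
        meta <- fromJSON(metas[k], simplifyVector = FALSE)
        meta_to_segment(meta, ecg[, k], ppg[, k], abp[, k])
      })
      segs <- segs[order(vapply(segs, `[[`, numeric(1), "t0"))]
      out[[sid]] <- list(
        subject_id = sid, age = segs[[1]]$age, sex = segs[[1]]$sex,
        segments = segs
      )
    }
    rhdf5::h5closeAll()
  }
  out
}

#' Train/validation/test subject split
#'
#' @param train_ids,validation_ids,test_ids Disjoint, non-empty character
#'   vectors of subject ids.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train_ids, validation_ids, test_ids) {
  sets <- list(train = train_ids, validation = validation_ids,
               test = test_ids)
  if (any(vapply(sets, length, integer(1)) == 0)) {
    stop("all three id sets must be non-empty")
  }
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) {
    stop("subject id sets must be pairwise disjoint")
  }
  structure(sets, class = "dataset_split")
}

#' @rdname dataset_split
#' @param split A `dataset_split`.
#' @param path JSON file path.
#' @export
save_split <- function(split, path) {
  write_json(unclass(split), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname dataset_split
#' @export
load_split <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  dataset_split(x$train, x$validation, x$test)
}

#' Randomly select per-subject segments for training, validation and testing
#'
#' Draws three disjoint random subsets from a subject's (QC-passing) segment
#' list. The test subset is re-sorted into temporal order, since the
#' personalization protocol requires its segments numbered sequentially in
#' time. A subject with fewer than `n_train + n_val + n_test` segments is
#' skipped: the function warns and returns `NULL`.
#'
#' @param segments List of [waveform_segment()]s in temporal order.
#' @param n_train,n_val,n_test Subset sizes (defaults 19, 7, 7).
#' @param seed Selection seed.
#' @return `list(train, validation, test)` of segment lists, or `NULL`.
#' @export
select_segments <- function(segments, n_train = 19, n_val = 7, n_test = 7,
                            seed = 1L) {
  need <- n_train + n_val + n_test
  if (length(segments) < need) {
    warning(
      "subject ", segments[[1]]$subject_id %||% "?", " skipped: ",
      length(segments), " segments available, ", need, " required"
    )
    return(NULL)
  }
  idx <- with_seed(seed, sample(length(segments), need))
  tr <- idx[seq_len(n_train)]
  va <- idx[n_train + seq_len(n_val)]
  te <- idx[n_train + n_val + seq_len(n_test)]
  te <- te[order(vapply(segments[te], `[[`, numeric(1), "t0"))]
  list(
    train = segments[tr], validation = segments[va], test = segments[te]
  )
}
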