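"""Independent numpy implementation of the canonical 22-feature set.

Used by the test suite as a cross-language oracle for the package's C++
feature engine. Reads a JSON list of numeric series on stdin (or a file path
given as argv[1]) and writes a JSON list of 22-element feature vectors.

Conventions (z-scoring with the population SD, bin-edge placement, the
single-interior-knot least-squares cubic spline, the two-regime split
criterion) follow the same published feature definitions as the C++ code but
are implemented independently with numpy linear algebra and vectorized
operations.
"""

import json
import sys

import numpy as np


def acf_fft(z):
    n = len(z)
    zc = z - z.mean()
    nfft = 1 << (2 * n - 1).bit_length()
    f = np.fft.rfft(zc, nfft)
    ac = np.fft.irfft(f * np.conj(f), nfft)[:n]
    if ac[0] <= 0:
        return np.zeros(n)
    return ac / ac[0]


def first_zero_ac(acf):
    below = np.flatnonzero(acf[1:] < 0)
    return int(below[0] + 1) if below.size else len(acf)


def ternarize(x):
    m = len(x)
    s = np.sort(x)
    th1 = s[int(np.ceil(m / 3.0)) - 1]
    th2 = s[int(np.ceil(2.0 * m / 3.0)) - 1]
    return np.where(x <= th1, 0, np.where(x <= th2, 1, 2))


def hist_counts(x, lo, hi, nbins):
    w = (hi - lo) / nbins
    b = np.floor((x - lo) / w).astype(int) if w > 0 else np.zeros(len(x), int)
    b = np.clip(b, 0, nbins - 1)
    return np.bincount(b, minlength=nbins)


def histogram_mode(z, nbins):
    lo, hi = z.min(), z.max()
    cnt = hist_counts(z, lo, hi, nbins)
    w = (hi - lo) / nbins
    centers = lo + w * (np.arange(nbins) + 0.5)
    return centers[cnt == cnt.max()].mean()


def f1ecac(acf):
    th = np.exp(-1.0)
    below = np.flatnonzero(acf[1:] < th)
    if not below.size:
        return float(len(acf))
    k = int(below[0] + 1)
    prev = acf[k - 1]
    return (k - 1) + (prev - th) / (prev - acf[k])


def first_min_ac(acf):
    interior = acf[1:-1]
    mins = np.flatnonzero((interior < acf[:-2]) & (interior < acf[2:]))
    return float(mins[0] + 1) if mins.size else float(len(acf))


def histogram_ami_even(z, tau=2, nbins=5):
    lo, hi = z.min() - 0.1, z.max() + 0.1
    w = (hi - lo) / nbins
    b1 = np.clip(np.floor((z[:-tau] - lo) / w).astype(int), 0, nbins - 1)
    b2 = np.clip(np.floor((z[tau:] - lo) / w).astype(int), 0, nbins - 1)
    joint = np.bincount(b1 * nbins + b2, minlength=nbins * nbins)
    joint = joint.reshape(nbins, nbins) / len(b1)
    p1 = joint.sum(axis=1)
    p2 = joint.sum(axis=0)
    mask = joint > 0
    outer = np.outer(p1, p2)
    return float(np.sum(joint[mask] * np.log(joint[mask] / outer[mask])))


def longest_run(b):
    # longest run of True
    padded = np.concatenate(([False], b, [False]))
    edges = np.flatnonzero(np.diff(padded.astype(int)))
    if not edges.size:
        return 0.0
    return float((edges[1::2] - edges[::2]).max())


def transition_matrix_3ac(z, acf):
    tau = first_zero_ac(acf)
    ds = z[::tau]
    if len(ds) < 4:
        return np.nan
    sym = ternarize(ds)
    pairs = sym[:-1] * 3 + sym[1:]
    T = np.bincount(pairs, minlength=9).reshape(3, 3) / (len(sym) - 1)
    return float(np.cov(T.T, ddof=1).trace())


def spline_detrend(z):
    n = len(z)
    t = np.arange(n) / (n - 1)
    tk = np.maximum(t - 0.5, 0.0)
    X = np.column_stack([np.ones(n), t, t**2, t**3, tk**3])
    beta, *_ = np.linalg.lstsq(X, z, rcond=None)
    return z - X @ beta


def periodicity_wang(z, th=0.01):
    acf = acf_fft(spline_detrend(z))
    maxtau = len(z) // 3
    seen_trough = False
    for k in range(1, min(maxtau, len(acf) - 1)):
        trough = acf[k] < acf[k - 1] and acf[k] < acf[k + 1]
        peak = acf[k] > acf[k - 1] and acf[k] > acf[k + 1]
        if trough:
            seen_trough = True
        if seen_trough and peak and acf[k] > th:
            return float(k)
    return 0.0


def embed2_dist_expfit(z, acf):
    n = len(z)
    tau = min(first_zero_ac(acf), n // 10)
    tau = max(tau, 1)
    m = n - tau
    d = np.hypot(np.diff(z[:m]), np.diff(z[tau:tau + m]))
    l = d.mean()
    if l <= 0:
        return np.nan
    nbins = int(np.ceil(np.sqrt(len(d))))
    lo, hi = d.min(), d.max()
    if hi <= lo:
        return np.nan
    cnt = hist_counts(d, lo, hi, nbins)
    w = (hi - lo) / nbins
    centers = lo + w * (np.arange(nbins) + 0.5)
    dens = cnt / (len(d) * w)
    return float(np.mean(np.abs(dens - np.exp(-centers / l) / l)))


def automutual_fmmi(acf):
    T = min(40, len(acf) // 2)
    r = np.clip(acf[1:T + 1], -0.999999, 0.999999)
    ami = -0.5 * np.log(1 - r**2)
    for k in range(1, T - 1):  # ami index k corresponds to lag k+1
        if ami[k] < ami[k - 1] and ami[k] < ami[k + 1]:
            return float(k + 1)
    return float(T)


def localsimple_mean1_tauresrat(z, acf):
    e = np.diff(z)
    return first_zero_ac(acf_fft(e)) / first_zero_ac(acf)


def localsimple_mean3_stderr(z):
    n = len(z)
    pred = (z[0:n - 3] + z[1:n - 2] + z[2:n - 1]) / 3.0
    e = z[3:] - pred
    return float(np.std(e, ddof=1))


def outlier_include_mdrmd(z, neg):
    y = -z if neg else z
    n = len(y)
    ymax = y.max()
    if ymax < 0:
        return np.nan
    relmed = []
    th = 0.0
    while th <= ymax:
        idx = np.flatnonzero(y >= th)
        if len(idx) < max(2, 0.02 * n):
            break
        relmed.append(np.median(idx) / ((n - 1) / 2.0) - 1.0)
        th += 0.01
    return float(np.median(relmed)) if relmed else np.nan


def welch_rect(z):
    n = len(z)
    nfft = max(256, 1 << (n - 1).bit_length())
    f = np.fft.rfft(z - z.mean(), nfft)
    S = np.abs(f) ** 2 / (2 * np.pi * n)
    nw = len(S)
    dw = 2 * np.pi / nfft
    area_5_1 = S[: nw // 5].sum() * dw
    cs = np.cumsum(S)
    over = np.flatnonzero(cs > 0.5 * cs[-1])
    centroid = (over[0] if over.size else nw - 1) * dw
    return float(area_5_1), float(centroid)


def motif_three_hh(z):
    sym = ternarize(z)
    pairs = sym[:-1] * 3 + sym[1:]
    p = np.bincount(pairs, minlength=9) / len(pairs)
    p = p[p > 0]
    return float(-(p * np.log(p)).sum())


def _linefit_sse(x, y):
    X = np.column_stack([np.ones(len(x)), x])
    beta, *_ = np.linalg.lstsq(X, y, rcond=None)
    r = y - X @ beta
    return float(r @ r)


def fluct_anal_prop_r1(z, lag, rsrange):
    x = z[::lag]
    N = len(x)
    cs = np.cumsum(x - x.mean())
    lo, hi = np.log(5.0), np.log(N / 2.0)
    xv = np.exp(lo + (hi - lo) * np.arange(50) / 49.0)
    xv = np.floor(xv * 1e6 + 0.5) / 1e6  # snap: grid reproducible across libms
    taus = np.unique(np.floor(xv + 0.5).astype(int))
    taus = taus[(taus >= 5) & (taus <= N // 2)]
    if len(taus) < 6:
        return np.nan
    logF = []
    for tau in taus:
        nbuf = N // tau
        B = cs[: nbuf * tau].reshape(nbuf, tau)
        t = np.arange(tau, dtype=float)
        X = np.column_stack([np.ones(tau), t])
        beta, *_ = np.linalg.lstsq(X, B.T, rcond=None)
        R = B.T - X @ beta
        if rsrange:
            stat = (R.max(axis=0) - R.min(axis=0)) ** 2
        else:
            stat = (R**2).mean(axis=0)
        logF.append(np.log(max(np.sqrt(stat.mean()), 1e-300)))
    logF = np.array(logF)
    logt = np.log(taus.astype(float))
    ntau = len(taus)
    best, bestsplit = np.inf, 3
    for s in range(3, ntau - 2):
        crit = (_linefit_sse(logt[:s], logF[:s]) / s
                + _linefit_sse(logt[s:], logF[s:]) / (ntau - s))
        if crit < best:
            best, bestsplit = crit, s
    return bestsplit / ntau


def catch22(series):
    x = np.asarray(series, dtype=float)
    n = len(x)
    sd = x.std()  # population SD
    if sd <= 0:
        return [np.nan] * 22
    z = (x - x.mean()) / sd
    acf = acf_fft(z)
    area, centroid = welch_rect(z)
    feats = [
        histogram_mode(z, 5),
        histogram_mode(z, 10),
        f1ecac(acf),
        first_min_ac(acf),
        histogram_ami_even(z),
        float(np.mean(np.diff(z) ** 3)),
        float(np.mean(np.abs(np.diff(z)) > 0.04)),
        longest_run(z > z.mean()),
        longest_run(np.diff(z) < 0),
        transition_matrix_3ac(z, acf),
        periodicity_wang(z),
        embed2_dist_expfit(z, acf),
        automutual_fmmi(acf),
        localsimple_mean1_tauresrat(z, acf),
        localsimple_mean3_stderr(z),
        outlier_include_mdrmd(z, False),
        outlier_include_mdrmd(z, True),
        area,
        centroid,
        motif_three_hh(z),
        fluct_anal_prop_r1(z, 2, False),
        fluct_anal_prop_r1(z, 1, True),
    ]
    return [None if np.isnan(v) else float(v) for v in feats]


def main():
    if len(sys.argv) > 1:
        with open(sys.argv[1]) as fh:
            series_list = json.load(fh)
    else:
        series_list = json.load(sys.stdin)
    json.dump([catch22(s) for s in series_list], sys.stdout)


if __name__ == "__main__":
    main()
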