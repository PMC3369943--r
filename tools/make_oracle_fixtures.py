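#!/usr/bin/env python
"""Generate frozen oracle fixtures for the test suite.

Two independent oracles, deliberately different algorithms from the package's
iterative-proportional-fitting solver:

1. A generic constrained entropy maximizer (SciPy trust-constr on the primal
   problem): maximize -sum(p log p) over an 8x8 count grid subject to fixed
   row/column marginals (truncated, renormalized Poisson) and a fixed
   product moment E[XY] implied by a target Pearson correlation.
   Output: tests/testthat/oracle_maxent_tables.csv

2. A linear program (scipy linprog, HiGHS) for the extreme attainable
   E[XY] over all couplings of fixed marginals on a 6x6 grid, giving the
   attainable Pearson correlation range.
   Output: tests/testthat/oracle_frechet_range.csv
"""
import numpy as np
from scipy import optimize, stats

OUT_DIR = "tests/testthat"


def trunc_pois(rate, K):
    p = stats.poisson.pmf(np.arange(K + 1), rate)
    return p / p.sum()


def maxent_oracle(rate_x, rate_y, rho, K=7):
    px = trunc_pois(rate_x, K)
    py = trunc_pois(rate_y, K)
    i = np.arange(K + 1)
    mux, muy = (i * px).sum(), (i * py).sum()
    vx = (i * i * px).sum() - mux ** 2
    vy = (i * i * py).sum() - muy ** 2
    target = rho * np.sqrt(vx * vy) + mux * muy
    IJ = np.outer(i, i).ravel()
    n = (K + 1) ** 2

    def negent(p):
        q = np.maximum(p, 1e-300)
        return (q * np.log(q)).sum()

    def negent_grad(p):
        q = np.maximum(p, 1e-300)
        return np.log(q) + 1.0

    A_rows = np.zeros((K + 1, n))
    A_cols = np.zeros((K + 1, n))
    for a in range(K + 1):
        A_rows[a, a * (K + 1):(a + 1) * (K + 1)] = 1.0
        A_cols[a, a::(K + 1)] = 1.0
    # drop the last column constraint: implied by the others (rank deficiency)
    A = np.vstack([A_rows, A_cols[:-1], IJ])
    b = np.concatenate([px, py[:-1], [target]])

    cons = [{"type": "eq", "fun": lambda p, A=A, b=b: A @ p - b,
             "jac": lambda p, A=A: A}]
    p0 = np.outer(px, py).ravel()
    res = optimize.minimize(negent, p0, jac=negent_grad, method="SLSQP",
                            bounds=[(1e-13, 1)] * n, constraints=cons,
                            options={"maxiter": 5000, "ftol": 1e-14})
    assert res.success, res.message
    resid = np.abs(A @ res.x - b).max()
    assert resid < 1e-9, resid
    return res.x


def main():
    rows = []
    K = 7
    cases = [(3.0, 3.0, -0.3), (3.0, 3.0, 0.0), (3.0, 3.0, 0.2),
             (3.0, 3.0, 0.5), (2.5, 3.5, 0.2)]
    for rx, ry, rho in cases:
        p = maxent_oracle(rx, ry, rho, K)
        for idx, val in enumerate(p):
            rows.append((rx, ry, rho, idx // (K + 1), idx % (K + 1), val))
    with open(f"{OUT_DIR}/oracle_maxent_tables.csv", "w") as f:
        f.write("rate_x,rate_y,rho,i,j,p\n")
        for r in rows:
            f.write("%g,%g,%g,%d,%d,%.15e\n" % r)

    # LP Frechet bounds on a 6x6 grid
    K = 5
    out = []
    for rx, ry in [(3.0, 3.0), (2.0, 4.0)]:
        px = trunc_pois(rx, K)
        py = trunc_pois(ry, K)
        i = np.arange(K + 1)
        mux, muy = (i * px).sum(), (i * py).sum()
        vx = (i * i * px).sum() - mux ** 2
        vy = (i * i * py).sum() - muy ** 2
        IJ = np.outer(i, i).ravel()
        n = (K + 1) ** 2
        A_rows = np.zeros((K + 1, n))
        A_cols = np.zeros((K + 1, n))
        for a in range(K + 1):
            A_rows[a, a * (K + 1):(a + 1) * (K + 1)] = 1.0
            A_cols[a, a::(K + 1)] = 1.0
        A = np.vstack([A_rows, A_cols])
        b = np.concatenate([px, py])
        lo = optimize.linprog(IJ, A_eq=A, b_eq=b, bounds=(0, 1),
                              method="highs")
        hi = optimize.linprog(-IJ, A_eq=A, b_eq=b, bounds=(0, 1),
                              method="highs")
        assert lo.status == 0 and hi.status == 0
        sd2 = np.sqrt(vx * vy)
        out.append((rx, ry,
                    (lo.fun - mux * muy) / sd2,
                    (-hi.fun - mux * muy) / sd2))
    with open(f"{OUT_DIR}/oracle_frechet_range.csv", "w") as f:
        f.write("rate_x,rate_y,rho_min,rho_max\n")
        for r in out:
            f.write("%g,%g,%.12f,%.12f\n" % r)
    print("wrote oracle fixtures")


if __name__ == "__main__":
    main()
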