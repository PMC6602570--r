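#!/usr/bin/env python
"""Independent linear-programming oracle for the flow tests.

Reads a JSON list of flow problems from argv[1] and writes a JSON list of
results to argv[2].  Each problem is solved twice with scipy.linprog
(HiGHS), in two formulations:

  arc:  minimize sum(cost*flow) - gamma*outflow(S) over arc flows, subject
        to flow conservation at every node except S and T and
        0 <= flow <= cap;
  path: minimize sum((cost_p - gamma) * f_p) over the flows of the
        pre-enumerated simple S->T paths, subject to per-arc capacity
        constraints and f_p >= 0 (exhaustive path-decomposition optimum;
        valid because all arc costs are non-negative, so cycles never
        improve the objective).

Input problem fields: n (nodes), S, T (1-based), gamma,
arcs = [[from, to, cap, cost], ...] (1-based),
paths = [[arc_index, ...], ...] (1-based, optional).
Output per problem: {"objective_arc": x, "objective_path": y or None}.

This script is test tooling only; the package itself never calls it.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_arc(prob):
    arcs = prob["arcs"]
    n, S, T = prob["n"], prob["S"], prob["T"]
    gamma = prob["gamma"]
    m = len(arcs)
    c = np.array([a[3] for a in arcs], dtype=float)
    for j, a in enumerate(arcs):
        if a[0] == S:
            c[j] -= gamma
    A = np.zeros((n, m))
    for j, a in enumerate(arcs):
        A[a[0] - 1, j] -= 1.0
        A[a[1] - 1, j] += 1.0
    keep = [i for i in range(n) if i not in (S - 1, T - 1)]
    A_eq = A[keep, :]
    b_eq = np.zeros(len(keep))
    bounds = [(0.0, a[2]) for a in arcs]
    res = linprog(c, A_eq=A_eq, b_eq=b_eq, bounds=bounds, method="highs")
    if not res.success:
        raise RuntimeError(f"arc LP failed: {res.message}")
    return float(res.fun)


def solve_path(prob):
    paths = prob.get("paths")
    if paths is None:
        return None
    arcs = prob["arcs"]
    gamma = prob["gamma"]
    if len(paths) == 0:
        return 0.0
    k = len(paths)
    cost_p = np.array([sum(arcs[j - 1][3] for j in p) for p in paths])
    c = cost_p - gamma
    A_ub = np.zeros((len(arcs), k))
    for pi, p in enumerate(paths):
        for j in p:
            A_ub[j - 1, pi] += 1.0
    b_ub = np.array([a[2] for a in arcs], dtype=float)
    bounds = [(0.0, None)] * k
    res = linprog(c, A_ub=A_ub, b_ub=b_ub, bounds=bounds, method="highs")
    if not res.success:
        raise RuntimeError(f"path LP failed: {res.message}")
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    out = []
    for prob in problems:
        out.append({
            "objective_arc": solve_arc(prob),
            "objective_path": solve_path(prob),
        })
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
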