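"""Solve one LP read from a JSON file and write the result as JSON.

Usage: python lp_solve.py problem.json result.json

Problem schema (all arrays plain lists; sparse matrices in triplet form):
  {"sense": "max"|"min", "c": [...],
   "A_ub": {"i": [...], "j": [...], "x": [...], "nrow": m, "ncol": n} | null,
   "b_ub": [...] | null, "A_eq": {...} | null, "b_eq": [...] | null,
   "lb": [...], "ub": [...]}
Bounds with magnitude >= 1e29 are treated as infinite.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog

INF_SENTINEL = 1e29


def triplet(d):
    if d is None or d["nrow"] == 0:
        return None
    return sparse.coo_matrix(
        (np.asarray(d["x"], dtype=float),
         (np.asarray(d["i"], dtype=int), np.asarray(d["j"], dtype=int))),
        shape=(d["nrow"], d["ncol"]),
    ).tocsr()


def main(problem_path, result_path):
    with open(problem_path) as fh:
        prob = json.load(fh)

    c = np.asarray(prob["c"], dtype=float)
    sense = prob.get("sense", "min")
    if sense == "max":
        c = -c

    A_ub = triplet(prob.get("A_ub"))
    b_ub = np.asarray(prob["b_ub"], dtype=float) if A_ub is not None else None
    A_eq = triplet(prob.get("A_eq"))
    b_eq = np.asarray(prob["b_eq"], dtype=float) if A_eq is not None else None

    lb = np.asarray(prob["lb"], dtype=float)
    ub = np.asarray(prob["ub"], dtype=float)
    lb[lb <= -INF_SENTINEL] = -np.inf
    ub[ub >= INF_SENTINEL] = np.inf
    bounds = np.column_stack([lb, ub])

    res = linprog(
        c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq, bounds=bounds,
        method="highs",
        options={
            "primal_feasibility_tolerance": 1e-10,
            "dual_feasibility_tolerance": 1e-10,
        },
    )

    status_map = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                  3: "unbounded", 4: "numerical"}
    status = status_map.get(res.status, "unknown")
    objective = None
    x = None
    if res.status == 0:
        objective = float(res.fun)
        if sense == "max":
            objective = -objective
        x = [float(v) for v in res.x]

    with open(result_path, "w") as fh:
        json.dump({"status": status, "objective": objective, "x": x,
                   "message": res.message}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
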