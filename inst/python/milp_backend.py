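"""Generic MILP enumeration backend.

Reads a JSON model description, solves it with scipy's HiGHS-backed MILP
solver, and enumerates alternative solutions by integer cuts over a declared
set of binary indicator variables: after each incumbent with active indicator
set A, the cut  sum_{a in A} y_a - sum_{a not in A} y_a <= |A| - 1  excludes
exactly that indicator pattern (not its supersets), and the loop re-solves
until k solutions are collected or the model becomes infeasible.

Usage: python milp_backend.py MODEL_JSON OUT_JSON
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def main(model_path, out_path):
    with open(model_path) as fh:
        m = json.load(fh)

    nvar = int(m["nvar"])
    c = np.asarray(m["objective"], dtype=float)
    lb = np.asarray(m["lb"], dtype=float)
    ub = np.asarray(m["ub"], dtype=float)
    lb[lb <= -INF] = -np.inf
    ub[ub >= INF] = np.inf

    rows = np.asarray(m["con"]["row"], dtype=int) - 1
    cols = np.asarray(m["con"]["col"], dtype=int) - 1
    vals = np.asarray(m["con"]["val"], dtype=float)
    ncon = int(m["con"]["nrow"])
    clb = np.asarray(m["con"]["lb"], dtype=float)
    cub = np.asarray(m["con"]["ub"], dtype=float)
    clb[clb <= -INF] = -np.inf
    cub[cub >= INF] = np.inf

    indicators = np.asarray(m.get("indicators", []), dtype=int) - 1
    k = int(m.get("max_solutions", 1))
    time_limit = float(m.get("time_limit", 300))
    options = {"mip_rel_gap": 0.0, "time_limit": time_limit}

    cut_rows = []  # each: (coef vector over indicators as dict col->val, rhs)
    solutions = []
    status = "ok"

    for _ in range(k):
        r = list(rows)
        co = list(cols)
        v = list(vals)
        cl = list(clb)
        cu = list(cub)
        nr = ncon
        for coef, rhs in cut_rows:
            for col, val in coef.items():
                r.append(nr)
                co.append(col)
                v.append(val)
            cl.append(-np.inf)
            cu.append(rhs)
            nr += 1
        if nr == 0:
            # unconstrained model: still run one solve with a dummy row
            A = sparse.csc_matrix((0, nvar))
            cons = []
        else:
            A = sparse.csc_matrix(
                (v, (r, co)), shape=(nr, nvar))
            cons = [LinearConstraint(A, np.asarray(cl), np.asarray(cu))]
        res = milp(
            c=c,
            constraints=cons,
            integrality=np.ones(nvar),
            bounds=Bounds(lb, ub),
            options=options,
        )
        if res.status == 2:  # infeasible
            if not solutions:
                status = "infeasible"
            break
        if res.status == 1:  # limits hit
            status = "partial"
            break
        if res.x is None:
            status = "error:" + str(res.message)
            break
        x = np.round(res.x).astype(int)
        solutions.append(
            {"x": x.tolist(), "objective": float(np.dot(c, x))}
        )
        if indicators.size == 0:
            break
        active = indicators[x[indicators] > 0]
        inactive = indicators[x[indicators] <= 0]
        coef = {int(a): 1.0 for a in active}
        coef.update({int(a): -1.0 for a in inactive})
        cut_rows.append((coef, float(len(active) - 1)))

    with open(out_path, "w") as fh:
        json.dump({"status": status, "solutions": solutions}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
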