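"""Batch MILP solver helper.

Reads a JSON file holding one or more mixed-integer linear programs in sparse
triplet form, solves each with scipy.optimize.milp (HiGHS branch-and-cut),
and writes a JSON list of results.

Usage: python milp_solve.py IN.json OUT.json

Input schema (all indices 1-based, as emitted by the R side):
  {"problems": [{
      "nvar": int,
      "obj": [float, ...],                  # length nvar
      "A": {"i": [...], "j": [...], "x": [...]},
      "con_lb": [...], "con_ub": [...],     # 1e30 encodes +/- infinity
      "var_lb": [...], "var_ub": [...],
      "integrality": [0/1, ...],
      "mip_gap": float, "time_limit": float
  }, ...]}

Output: [{"status": int, "message": str, "objective": float or null,
          "x": [...] or null, "mip_gap": float or null}, ...]
Status codes follow scipy: 0 optimal, 1 iteration/time limit reached,
2 infeasible, 3 unbounded, 4 other.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def _inf(v):
    a = np.asarray(v, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(p):
    nvar = int(p["nvar"])
    c = np.asarray(p["obj"], dtype=float)
    tri = p["A"]
    i = np.asarray(tri["i"], dtype=int) - 1
    j = np.asarray(tri["j"], dtype=int) - 1
    x = np.asarray(tri["x"], dtype=float)
    ncon = len(p["con_lb"])
    A = sp.csc_matrix((x, (i, j)), shape=(ncon, nvar))
    cons = LinearConstraint(A, _inf(p["con_lb"]), _inf(p["con_ub"]))
    bounds = Bounds(_inf(p["var_lb"]), _inf(p["var_ub"]))
    integrality = np.asarray(p["integrality"], dtype=int)
    options = {
        "mip_rel_gap": float(p.get("mip_gap", 1e-4)),
        "time_limit": float(p.get("time_limit", 3600.0)),
        "presolve": True,
    }
    res = milp(c=c, constraints=cons, integrality=integrality, bounds=bounds,
               options=options)
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "objective": None,
        "x": None,
        "mip_gap": None,
    }
    if res.x is not None:
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
        gap = getattr(res, "mip_gap", None)
        out["mip_gap"] = None if gap is None else float(gap)
    return out


def main(argv):
    if len(argv) != 3:
        sys.stderr.write(__doc__)
        return 2
    with open(argv[1]) as fh:
        payload = json.load(fh)
    results = [solve_one(p) for p in payload["problems"]]
    with open(argv[2], "w") as fh:
        json.dump(results, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
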