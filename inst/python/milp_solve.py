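"""Solve a (mixed-integer) linear program described as JSON.

Input JSON:
  ncol          number of variables
  obj           objective coefficients (minimize)
  lb, ub        variable bounds (null -> +/- inf)
  integrality   0 = continuous, 1 = integer, per variable
  row, col, val sparse constraint triplets (1-based indices)
  clb, cub      constraint row bounds (null -> +/- inf)
  time_limit    seconds (optional)
  mip_gap       relative gap tolerance (optional)

Output JSON: status (string), success (bool), objective, x (list or null).
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, milp, Bounds


def _arr(v, n, fill):
    if v is None:
        return np.full(n, fill, dtype=float)
    if not isinstance(v, list):
        v = [v]
    return np.asarray([fill if x is None else x for x in v], dtype=float)


def _vec(v, dtype=float):
    if v is None:
        return np.asarray([], dtype=dtype)
    if not isinstance(v, list):
        v = [v]
    return np.asarray(v, dtype=dtype)


def main(path_in, path_out):
    with open(path_in) as fh:
        m = json.load(fh)
    n = int(m["ncol"])
    obj = _vec(m["obj"])
    lb = _arr(m.get("lb"), n, -np.inf)
    ub = _arr(m.get("ub"), n, np.inf)
    integ = _vec(m.get("integrality", [0] * n), dtype=int)

    constraints = []
    nrow = int(m.get("nrow", 0))
    if nrow > 0:
        row = _vec(m["row"], dtype=int) - 1
        col = _vec(m["col"], dtype=int) - 1
        val = _vec(m["val"])
        A = sparse.csr_matrix((val, (row, col)), shape=(nrow, n))
        clb = _arr(m.get("clb"), nrow, -np.inf)
        cub = _arr(m.get("cub"), nrow, np.inf)
        constraints.append(LinearConstraint(A, clb, cub))

    options = {}
    if m.get("time_limit") is not None:
        options["time_limit"] = float(m["time_limit"])
    if m.get("mip_gap") is not None:
        options["mip_rel_gap"] = float(m["mip_gap"])

    res = milp(
        c=obj,
        constraints=constraints,
        integrality=integ,
        bounds=Bounds(lb, ub),
        options=options,
    )
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "success": bool(res.success),
        "objective": None if res.x is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
    }
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
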