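"""Independent LP oracle for the hinge + total-variation program.

Reads Z.csv, D.csv (already row-weighted), y.csv from the directory in
argv[1] and gamma from argv[2]; solves

    min ||D w||_1 + gamma * sum(eps)
    s.t. y_i (z_i' w + b) >= 1 - eps_i,  eps >= 0

via the standard linearisation with scipy's HiGHS solver and prints the
optimal objective.
"""
import sys

import numpy as np
import pandas as pd
from scipy.optimize import linprog

td = sys.argv[1]
gamma = float(sys.argv[2])
Z = pd.read_csv(f"{td}/Z.csv").values.astype(float)
D = pd.read_csv(f"{td}/D.csv").values.astype(float)
y = pd.read_csv(f"{td}/y.csv").y.values.astype(float)

n, ns = Z.shape
nds = D.shape[0]
c = np.concatenate([np.zeros(ns + 1), np.ones(nds), gamma * np.ones(n)])
A1 = np.hstack([-(Z * y[:, None]), -y[:, None], np.zeros((n, nds)), -np.eye(n)])
A2 = np.hstack([D, np.zeros((nds, 1)), -np.eye(nds), np.zeros((nds, n))])
A3 = np.hstack([-D, np.zeros((nds, 1)), -np.eye(nds), np.zeros((nds, n))])
A = np.vstack([A1, A2, A3])
b = np.concatenate([-np.ones(n), np.zeros(2 * nds)])
bounds = [(None, None)] * (ns + 1) + [(0, None)] * (nds + n)
res = linprog(c, A_ub=A, b_ub=b, bounds=bounds, method="highs")
assert res.status == 0, res.message
print("%.12f" % res.fun)
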