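"""Run HDBSCAN* (leaf cluster selection) on a CSV feature matrix.

Usage: python hdbscan_leaf.py IN_CSV OUT_CSV MIN_CLUSTER_SIZE MIN_SAMPLES

Writes one integer label per row to OUT_CSV (-1 = noise).
"""
import sys

import numpy as np
from sklearn.cluster import HDBSCAN


def main() -> None:
    in_csv, out_csv, mcs, ms = sys.argv[1:5]
    x = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    labels = HDBSCAN(
        min_cluster_size=int(mcs),
        min_samples=int(ms),
        cluster_selection_method="leaf",
    ).fit_predict(x)
    np.savetxt(out_csv, labels.astype(int), fmt="%d")


if __name__ == "__main__":
    main()
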