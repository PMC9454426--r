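"""densMAP embedding helper.

Usage: densmap_embed.py X.tsv y.txt out.tsv seed n_neighbors min_dist \
       target_weight dens_lambda

Reads a feature matrix (TSV, no header) and integer labels (one per
line), runs density-preserving UMAP (densMAP), supervised by the labels
when target_weight >= 0, and writes the 2-D coordinates as TSV.
"""
import sys

import numpy as np


def main(argv):
    (xp, yp, outp, seed, n_neighbors, min_dist, target_weight,
     dens_lambda) = argv[1:9]
    X = np.loadtxt(xp, delimiter="\t", ndmin=2)
    y = np.loadtxt(yp, dtype=int, ndmin=1)
    import umap  # deferred: slow import

    n_neighbors = min(int(n_neighbors), max(2, X.shape[0] - 1))
    kw = dict(
        n_components=2,
        n_neighbors=n_neighbors,
        min_dist=float(min_dist),
        densmap=True,
        dens_lambda=float(dens_lambda),
        random_state=int(seed),
        n_jobs=1,
    )
    reducer = umap.UMAP(**kw)
    tw = float(target_weight)
    if tw >= 0:
        reducer.target_weight = tw
        emb = reducer.fit_transform(X, y=y)
    else:
        emb = reducer.fit_transform(X)
    np.savetxt(outp, emb, delimiter="\t")


if __name__ == "__main__":
    main(sys.argv)
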