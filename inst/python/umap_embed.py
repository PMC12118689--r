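"""Subprocess bridge: 2-D UMAP embedding of a pixel-feature matrix.

Usage:
    python umap_embed.py IN N F OUT SEED N_NEIGHBORS MIN_DIST

IN  : little-endian float64 binary, N*F values, row-major
OUT : little-endian float64 binary, N*2 values, row-major
The embedding is deterministic for a fixed seed (random_state forces
single-threaded layout optimisation).
"""
import sys
import warnings

import numpy as np


def main(argv):
    infile, n, f, outfile, seed, n_neighbors, min_dist = argv
    n, f, seed = int(n), int(f), int(seed)
    X = np.fromfile(infile, dtype="<f8").reshape(n, f)
    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap
        emb = umap.UMAP(
            n_components=2,
            random_state=seed,
            n_neighbors=min(int(n_neighbors), n - 1),
            min_dist=float(min_dist),
        ).fit_transform(X)
    np.asarray(emb, dtype="<f8").tofile(outfile)


if __name__ == "__main__":
    main(sys.argv[1:])
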