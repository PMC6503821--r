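"""Independent coalescent oracle: two-deme divergence model in msprime.

Simulates replicate SNP datasets (one genealogy per locus, segregating sites
allocated across the replicate's genealogies proportional to total branch
length, one mutation uniform on the tree) and prints the mean pairwise
multilocus G_ST (Nei, ratio of across-locus averages) across replicates.

Usage: python msprime_gst.py N T_SPLIT N_DIP N_LOCI N_REPS SEED
"""
import sys

import msprime
import numpy as np


def main():
    N, t_split, n_dip, n_loci, n_reps, seed = (float(sys.argv[1]),
                                               float(sys.argv[2]),
                                               int(sys.argv[3]),
                                               int(sys.argv[4]),
                                               int(sys.argv[5]),
                                               int(sys.argv[6]))
    rng = np.random.default_rng(seed)
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=N)
    dem.add_population(name="B", initial_size=N)
    dem.add_population(name="anc", initial_size=N)
    dem.add_population_split(time=t_split, derived=["A", "B"], ancestral="anc")

    reps = msprime.sim_ancestry(
        samples={"A": n_dip, "B": n_dip}, demography=dem, ploidy=2,
        num_replicates=n_loci * n_reps, random_seed=seed)

    n = 2 * n_dip
    gst_vals = []
    trees = []
    lens = []
    for ts in reps:
        t = ts.first()
        trees.append(t)
        lens.append(t.total_branch_length)
        if len(trees) == n_loci:
            lens_a = np.array(lens)
            counts = rng.multinomial(n_loci, lens_a / lens_a.sum())
            pa, pb = [], []
            for tr, c in zip(trees, counts):
                if c == 0:
                    continue
                nodes = [u for u in tr.nodes() if tr.parent(u) != -1]
                bl = np.array([tr.branch_length(u) for u in nodes])
                for _ in range(c):
                    u = nodes[rng.choice(len(nodes), p=bl / bl.sum())]
                    carriers = set(tr.leaves(u))
                    da = sum(1 for s in carriers if s < n)
                    db = sum(1 for s in carriers if s >= n)
                    pa.append(da / n)
                    pb.append(db / n)
            pa = np.array(pa)
            pb = np.array(pb)
            hs = (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
            pbar = (pa + pb) / 2
            ht = 2 * pbar * (1 - pbar)
            gst_vals.append((ht.mean() - hs.mean()) / ht.mean())
            trees, lens = [], []

    print(np.mean(gst_vals))


if __name__ == "__main__":
    main()
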