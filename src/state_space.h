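#ifndef CODIV_STATE_SPACE_H
#define CODIV_STATE_SPACE_H

// Shared state-space indexing for partial-likelihood tables over
// (n, r) = (ancestral lineage count, lineages carrying the red allele).
// Index 0 is the empty state (0, 0); states with n >= 1 follow in
// lexicographic order: (1,0), (1,1), (2,0), ..., (nmax, nmax).

static inline int state_index(int n, int r) {
  if (n == 0) return 0;
  return 1 + (n - 1) * (n + 2) / 2 + r;
}

static inline int state_dim(int nmax) { return 1 + nmax * (nmax + 3) / 2; }

#endif
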