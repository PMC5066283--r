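# Build a ranked screen with the actives at given ranks.
make_screen <- function(N, act_ranks, target_id = "t") {
  ranked_screen(target_id, data.frame(
    compound_id = paste0("c", seq_len(N)),
    score = as.numeric(N:1),
    is_active = seq_len(N) %in% act_ranks))
}

# Independent direct-summation BEDROC oracle: a literal term-by-term
# transcription of the score's defining expression, kept free of the
# vectorized implementation under test.
bedroc_oracle <- function(act_ranks, N, alpha) {
  n <- length(act_ranks)
  Ra <- n / N
  acc <- 0
  for (r in act_ranks) acc <- acc + exp(-alpha * r / N)
  denom <- Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  fac <- Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra))
  acc / denom * fac + 1 / (1 - exp(alpha * (1 - Ra)))
}

# Tiny hand-enumerable molecules.
mol_ethane <- function()
  molecule("ethane", c("C", "C"), data.frame(a1 = 1, a2 = 2, order = 1))

mol_butane <- function()
  molecule("butane", rep("C", 4),
           data.frame(a1 = 1:3, a2 = 2:4, order = 1))

mol_isobutane <- function()
  molecule("isobutane", rep("C", 4),
           data.frame(a1 = c(2, 2, 2), a2 = c(1, 3, 4), order = 1))

# 2,2,3,3-tetramethylbutane: two quaternary carbons.
mol_tetramethylbutane <- function()
  molecule("tmb", rep("C", 8),
           data.frame(a1 = c(1, 2, 2, 2, 3, 3, 3),
                      a2 = c(2, 5, 6, 3, 4, 7, 8), order = 1))

mol_benzene <- function()
  molecule("benzene", rep("C", 6),
           data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))

mol_cyclohexane <- function()
  molecule("cyclohexane", rep("C", 6),
           data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1))

# Fingerprint with the given bit positions set (64 bits, shared dialect).
make_fp <- function(on, n_bits = 64L, dialect = "test/1") {
  bits <- logical(n_bits)
  bits[on] <- TRUE
  fingerprint(bits, dialect)
}

# Cavity with atoms at explicit distances from a single probe at origin.
cavity_at_distances <- function(d, elements = rep("C", length(d)),
                                cutoff = 4) {
  cavity_model(data.frame(id = seq_along(d), element = elements,
                          x = d, y = 0, z = 0),
               matrix(0, 1, 3), cutoff = cutoff)
}
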