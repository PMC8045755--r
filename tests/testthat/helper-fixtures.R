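# Shared fixtures built in code. Kept tiny; heavier simulations live in
# the tests that need them.

# a cohort with no planted structure at all
null_cohort <- function(n = 200L, seed = 1L) {
  generate_cohort(cohort_spec(n_patients = n, seed = seed))
}

# cohort with a 3-feature proportional-hazards signal
planted_surv_cohort <- function(n = 300L, beta = 0.8, seed = 1L) {
  generate_cohort(cohort_spec(
    n_patients = n,
    cox_betas = c(area_mean = beta, ratio_skewness = beta,
                  distMin_bin5 = -beta),
    seed = seed))
}

# cohort with one gene shifting one feature
planted_mut_cohort <- function(n = 200L, effect = 1.5, freq = 0.5,
                               seed = 1L) {
  generate_cohort(cohort_spec(
    n_patients = n,
    mutation_genes = data.frame(gene = "GENE1", frequency = freq,
                                feature = "area_mean", effect = effect),
    seed = seed))
}

# digitize a solid axis-aligned ellipse into a label mask
ellipse_mask <- function(a, b, pad = 4L) {
  h <- 2 * ceiling(b) + 2 * pad + 1
  w <- 2 * ceiling(a) + 2 * pad + 1
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  m <- matrix(0L, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w))
    if (((cc - cx) / a)^2 + ((r - cy) / b)^2 <= 1) m[r, cc] <- 1L
  m
}

flat_image <- function(mask, rgb = c(120, 60, 200)) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- ifelse(mask > 0, rgb[k], 255)
  img
}

# brute-force two-sided Mann-Whitney p-value by enumeration of labelings
mwu_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# brute-force BH q-values: sort, scale, cumulative min, map back
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
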