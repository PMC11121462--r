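# Minimal in-range sample row(s) for rule tests; override fields as needed.
make_samples <- function(n = 1, ...) {
  base <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    declared_type = "polyfloral",
    region = "Belgrade",
    year = 2020L,
    glu = 31, fru = 39,
    suc = 0.8, suc_censored = FALSE,
    hmf = 5, hmf_censored = FALSE,
    mc = 16.5, acid = 21, dia = 12.9, ins = 0.01,
    econd = 0.40
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# one fully reclassified row
make_final <- function(...) {
  s <- make_samples(1, ...)
  if (!"final_type" %in% names(s)) s$final_type <- s$declared_type
  s
}

# random valid tables for property-style tests
random_table <- function(n, seed) {
  set.seed(seed)
  make_samples(
    n,
    declared_type = sample(honey_types(), n, replace = TRUE),
    region = sample(honey_regions(), n, replace = TRUE),
    year = sample(honey_years(), n, replace = TRUE),
    glu = runif(n, 14, 44), fru = runif(n, 14, 53),
    suc = runif(n, 0.5, 17), hmf = runif(n, 0.5, 95),
    mc = runif(n, 13, 27), acid = runif(n, 2, 62),
    dia = runif(n, 0.5, 40), ins = runif(n, 0, 0.12),
    econd = runif(n, 0.02, 1.8)
  )
}
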