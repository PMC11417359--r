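# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a 200-gene two-sample dataset (80 repression / 60 induction / 60
# steady, a minority frozen) with WT and KO fits and inferred times
small_run <- function() fixture("small_run", function() {
  genes <- default_kinetic_genes(80, 60, 60, 30, 15, seed = 5)
  cfg <- simulation_config(n_cells_per_sample = 500, seed = 6)
  pair <- simulate_dataset(genes, cfg)
  wt <- subset_pair(pair, "WT")
  ko <- subset_pair(pair, "KO")
  mom_wt <- compute_moments(wt)
  mom_ko <- compute_moments(ko)
  fits_wt <- fit_all_genes(mom_wt, max_iter = 6)
  list(genes = genes, cfg = cfg, pair = pair, wt = wt, ko = ko,
       mom_wt = mom_wt, mom_ko = mom_ko, fits_wt = fits_wt,
       drivers = select_driver_genes(fits_wt),
       time_wt = inferred_cell_time(fits_wt),
       time_ko = inferred_cell_time(fits_wt,
                                    mu = size_normalize(ko$unspliced),
                                    ms = size_normalize(ko$spliced)))
})

# brute-force Mann-Kendall oracle: explicit pair enumeration plus the
# tie-corrected variance formula computed from first principles
mk_oracle <- function(x) {
  x <- unname(x)
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[j] - x[i])
  tie_sizes <- as.integer(table(x))
  tie_term <- 0
  for (t in tie_sizes) if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  varS <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  list(S = S, varS = varS)
}

# regular-expression motif oracle (both strands, overlapping matches)
iupac_regex <- function(pattern) {
  sets <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
            S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
            D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(sets[strsplit(pattern, "")[[1]]], collapse = "")
}

scan_oracle <- function(sequence, pattern) {
  w <- nchar(pattern)
  L <- nchar(sequence)
  fwd <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), sequence,
                  perl = TRUE)[[1]]
  fwd <- if (fwd[1] == -1) integer() else as.integer(fwd) - 1L
  rcseq <- revcomp(sequence)
  rev <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), rcseq,
                  perl = TRUE)[[1]]
  rev <- if (rev[1] == -1) integer() else L - (as.integer(rev) - 1L) - w
  list(fwd = sort(fwd), rev = sort(rev))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
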