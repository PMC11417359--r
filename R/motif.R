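IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x character scalar over IUPAC letters.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  unname(chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
                vapply(x, function(s)
                  paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")))
}

#' Declare a degenerate motif pattern
#'
#' Patterns are written in IUPAC one-letter codes; e.g. the heptamer
#' (T/A/C)(A/G)GAA(C/T)(G/C/A) is `"HRGAAYV"` and the octamer
#' GA(A/C)(C/G)C(T/G)(T/C)C is `"GAMSCKYC"`. Invalid letters are rejected
#' at construction.
#'
#' @param motif_id short identifier.
#' @param pattern nonempty IUPAC string.
#' @param strand_mode `"both"`, `"forward"` or `"reverse"`.
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(motif_id, pattern,
                          strand_mode = c("both", "forward", "reverse")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC letter(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  structure(list(motif_id = motif_id, pattern = toupper(pattern),
                 strand_mode = strand_mode),
            class = "motif_pattern")
}

# positions (0-based) where `letters` matches the IUPAC pattern; an N in
# the sequence never matches any pattern letter
match_positions <- function(letters, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  L <- length(pat); n <- length(letters)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & letters[seq_len(n - L + 1L) + j - 1L] %in% IUPAC_SETS[[pat[j]]]
  }
  which(ok) - 1L
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Reports every window satisfying the IUPAC pattern. Reverse-strand hits
#' are found by scanning the reverse complement of the pattern along the
#' forward sequence and are reported at the forward coordinate of the
#' window start; the `match` column holds the sequence read on the
#' reported strand. Sequence letters other than A/C/G/T (including N)
#' never match.
#'
#' @param sequence character scalar (case-insensitive DNA).
#' @param pattern a [motif_pattern()].
#' @return data.frame with columns `position` (0-based window start on the
#'   forward strand), `strand`, `match`, `motif_id`.
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq_up <- toupper(sequence)
  letters <- strsplit(seq_up, "")[[1]]
  L <- nchar(pattern$pattern)
  out <- list()
  if (pattern$strand_mode %in% c("both", "forward")) {
    pos <- match_positions(letters, pattern$pattern)
    if (length(pos))
      out[[1]] <- data.frame(position = pos, strand = "+",
                             match = substring(seq_up, pos + 1L, pos + L),
                             stringsAsFactors = FALSE)
  }
  if (pattern$strand_mode %in% c("both", "reverse")) {
    pos <- match_positions(letters, revcomp(pattern$pattern))
    if (length(pos))
      out[[2]] <- data.frame(position = pos, strand = "-",
                             match = unname(revcomp(
                               substring(seq_up, pos + 1L, pos + L))),
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(), strand = character(),
               match = character(), stringsAsFactors = FALSE)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  res$motif_id <- rep(pattern$motif_id, nrow(res))
  rownames(res) <- NULL
  res
}

# classify every 5-mer start: does its core (positions 2-4 of the unit)
# read GAA (forward) or TTC (reverse), exactly or with <= 1 mismatch
hse_unit_table <- function(letters) {
  n <- length(letters)
  if (n < 5L) return(NULL)
  starts <- seq_len(n - 4L)            # 1-based unit starts
  core <- cbind(letters[starts + 1L], letters[starts + 2L],
                letters[starts + 3L])
  mm_fwd <- (core[, 1] != "G") + (core[, 2] != "A") + (core[, 3] != "A") +
    0L + 3L * rowSums(matrix(!(core %in% c("A", "C", "G", "T")), ncol = 3))
  mm_rev <- (core[, 1] != "T") + (core[, 2] != "T") + (core[, 3] != "C") +
    0L + 3L * rowSums(matrix(!(core %in% c("A", "C", "G", "T")), ncol = 3))
  list(starts0 = starts - 1L, mm_fwd = mm_fwd, mm_rev = mm_rev)
}

#' Detect heat-shock elements (alternating nGAAn arrays)
#'
#' A heat-shock element (HSE) is a tandem array of at least `min_units`
#' adjacent nGAAn 5-mers at period 5 whose GAA cores alternate orientation
#' (GAA on one strand, TTC = reverse-complement orientation on the next).
#' In degenerate mode, up to `max_mismatch_units` units may carry one
#' mismatch in the three-letter core. Maximal runs are reported; runs
#' contained in a longer reported run on the same 5-bp frame are dropped.
#'
#' @param sequence character scalar DNA.
#' @param min_units minimum number of units (>= 2).
#' @param max_mismatch_units how many units may have one core mismatch.
#' @return data.frame with `position` (0-based start), `n_units`,
#'   `length` (bases), `first_unit` orientation (`"+"` for GAA, `"-"` for
#'   TTC).
#' @export
detect_hse <- function(sequence, min_units = 3L, max_mismatch_units = 0L) {
  if (min_units < 2L) stop("min_units must be >= 2")
  letters <- strsplit(toupper(sequence), "")[[1]]
  tab <- hse_unit_table(letters)
  if (is.null(tab))
    return(data.frame(position = integer(), n_units = integer(),
                      length = integer(), first_unit = character()))
  n_units_avail <- length(tab$starts0)
  runs <- list()
  for (i in seq_len(n_units_avail)) {
    for (ori in c("+", "-")) {
      k <- 0L; budget <- max_mismatch_units
      repeat {
        idx <- i + 5L * k
        if (idx > n_units_avail) break
        mm <- if (xor(ori == "-", k %% 2L == 0L)) tab$mm_fwd[idx]
              else tab$mm_rev[idx]
        # k even keeps the starting orientation, k odd flips it
        if (mm == 0L) k <- k + 1L
        else if (mm == 1L && budget > 0L) { budget <- budget - 1L; k <- k + 1L }
        else break
      }
      if (k >= min_units)
        runs[[length(runs) + 1L]] <-
          data.frame(position = tab$starts0[i], n_units = k,
                     length = 5L * k, first_unit = ori,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(runs))
    return(data.frame(position = integer(), n_units = integer(),
                      length = integer(), first_unit = character()))
  res <- unique(do.call(rbind, runs))
  # keep only maximal runs: drop runs contained in a longer one on the
  # same 5-bp frame
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i == j || !keep[i]) next
      same_frame <- (res$position[i] - res$position[j]) %% 5L == 0L
      contained <- res$position[j] <= res$position[i] &&
        res$position[j] + res$length[j] >= res$position[i] + res$length[i] &&
        res$length[j] > res$length[i]
      if (same_frame && contained) keep[i] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$position, res$first_unit), , drop = FALSE]
  rownames(res) <- NULL
  res
}
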