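# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so deterministic fixture
#' builders do not disturb user-level random streams.
#' @noRd
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Three-letter amino-acid codes used by the HGVS-p-lite formatter.
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' @noRd
aa3 <- function(x) unname(AA_THREE[x])

#' Translate a CDS up to (not including) the first stop codon
#'
#' Uses the standard codon table. Trailing incomplete codons are ignored.
#' Returns the residue vector, whether a stop was reached, and the codon
#' index of the stop.
#' @noRd
translate_to_stop <- function(dna, require_atg = TRUE) {
  n <- nchar(dna)
  if (n < 3L) stop("CDS shorter than one codon")
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  if (require_atg && codons[1L] != "ATG")
    stop("non-ATG start codon unsupported")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("CDS contains ambiguous or non-ACGT bases")
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(aa = aa[seq_len(stop_at[1L] - 1L)], terminated = TRUE,
         stop_index = stop_at[1L])
  } else {
    list(aa = aa, terminated = FALSE, stop_index = NA_integer_)
  }
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
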