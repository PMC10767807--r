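#' Default thresholds and parameters of the prediction pipeline
#'
#' Single source of truth for every numeric threshold used by the pipeline.
#' Stage functions reference these values through their default arguments, so
#' changing a value here (or passing an override) changes the behaviour of
#' the whole pipeline consistently.
#'
#' @return A named list:
#' \describe{
#'   \item{h_value}{Candidate retention cut-off on the H-value
#'     (identity x query coverage); hits are kept when strictly greater
#'     (default 0.36).}
#'   \item{len_min, len_max}{Inclusive bounds on toxin/antitoxin protein
#'     length in amino acids (default 30 and 500).}
#'   \item{evalue_blast}{Permissive raw E-value ceiling for reporting
#'     protein/nucleotide alignment hits (default 0.01).}
#'   \item{evalue_hmm}{E-value threshold for domain-profile hits
#'     (default 1e-5).}
#'   \item{flank_bp}{Maximum TA-to-IS interval, exclusive, for a
#'     flanking association (default 5000 bp).}
#'   \item{mash_threshold}{Mash distance below which two mobile elements
#'     are called similar, strict (default 0.01).}
#'   \item{k}{k-mer size for MinHash sketches (default 21).}
#'   \item{s}{sketch size, number of retained minimum hashes
#'     (default 1000).}
#'   \item{hash_seed}{fixed seed of the sketch hash function (42).}
#'   \item{seed}{default seed for stochastic steps such as synthetic
#'     genome generation (42).}
#' }
#' @export
#' @examples
#' ta_defaults()$h_value
ta_defaults <- function() {
  list(
    h_value        = 0.36,
    len_min        = 30L,
    len_max        = 500L,
    evalue_blast   = 0.01,
    evalue_hmm     = 1e-5,
    flank_bp       = 5000L,
    mash_threshold = 0.01,
    k              = 21L,
    s              = 1000L,
    hash_seed      = 42L,
    seed           = 42L
  )
}
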