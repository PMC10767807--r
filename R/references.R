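## Reference sets of validated toxin/antitoxin sequences.
##
## FASTA headers carry structured metadata, pipe-separated:
##   >ref_id|role|type|family
## e.g. ">relE_syn|toxin|II|relBE". role is toxin/antitoxin; type is the
## roman TA type I..VIII; family the TA family name.

ROMAN_TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

#' Read a toxin/antitoxin reference FASTA
#'
#' Headers must follow the `ref_id|role|type|family` convention. Protein
#' and RNA reference sets live in separate files; `molecule` tags which one
#' is being read.
#'
#' @param path FASTA file path.
#' @param molecule `"protein"` or `"rna"`.
#' @return data.frame with columns `ref_id`, `role`, `ta_type`, `family`,
#'   `molecule`, `sequence`.
#' @export
read_reference_fasta <- function(path, molecule = c("protein", "rna")) {
  molecule <- match.arg(molecule)
  set <- if (molecule == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty reference FASTA: ", path)
  parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("reference headers must be 'ref_id|role|type|family'; offending: ",
         paste(vapply(parts[bad], paste, "", collapse = "|"), collapse = ", "))
  m <- do.call(rbind, parts)
  if (!all(m[, 2] %in% c("toxin", "antitoxin")))
    stop("reference role must be toxin or antitoxin")
  if (!all(m[, 3] %in% ROMAN_TYPES))
    stop("reference TA type must be one of ", paste(ROMAN_TYPES, collapse = ","))
  data.frame(ref_id = m[, 1], role = m[, 2], ta_type = m[, 3],
             family = m[, 4], molecule = molecule,
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bundled synthetic reference set
#'
#' Loads the package's bundled reference toxins/antitoxins covering all
#' eight TA types. These sequences are synthetic stand-ins generated with
#' realistic lengths and residue composition, one pair (or
#' protein-plus-RNA pair) per family; they let every stage of the pipeline
#' run and be tested end to end, but they are not the curated sequences of
#' real TA families.
#'
#' @return A list with data.frames `protein` and `rna`, each as returned by
#'   [read_reference_fasta()].
#' @export
bundled_references <- function() {
  list(
    protein = read_reference_fasta(
      system.file("extdata", "synthetic_ta_refs_protein.faa",
                  package = "tascan", mustWork = TRUE), "protein"),
    rna = read_reference_fasta(
      system.file("extdata", "synthetic_ta_refs_rna.fna",
                  package = "tascan", mustWork = TRUE), "rna"))
}
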