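## Pipeline orchestration: stage commands communicating through TSVs on
## disk, a key-value (DCF) run configuration, and a JSON run manifest.

#' Run configuration
#'
#' Builds the configuration of a pipeline run: input/output paths plus
#' the thresholds of [ta_defaults()]. Any threshold override is recorded
#' and echoed to the run manifest. Configurations can also be read from a
#' key-value file in DCF format (`field: value` lines) whose field names
#' mirror this function's arguments exactly.
#'
#' @param genome_fasta,genome_gff FASTA + GFF3 genome input (or ...)
#' @param genome_genbank a GenBank flat file genome input.
#' @param refs_protein,refs_rna reference FASTA paths; NULL selects the
#'   bundled synthetic reference set.
#' @param profiles optional HMMER3 profile file for the domain scan.
#' @param mge_table MGE annotation TSV/GFF3 path.
#' @param rules optional rules TSV overriding the bundled pairing table.
#' @param out_dir output directory of every stage.
#' @param require_blast stringent mode: domain evidence alone never
#'   retains a candidate.
#' @param ... threshold overrides, by [ta_defaults()] name.
#' @return List of class `ta_config`.
#' @export
ta_config <- function(genome_fasta = NULL, genome_gff = NULL,
                      genome_genbank = NULL, refs_protein = NULL,
                      refs_rna = NULL, profiles = NULL, mge_table = NULL,
                      rules = NULL, out_dir = "tascan_out",
                      require_blast = FALSE, ...) {
  defs <- ta_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  thresholds <- utils::modifyList(defs, over)
  structure(list(genome_fasta = genome_fasta, genome_gff = genome_gff,
                 genome_genbank = genome_genbank,
                 refs_protein = refs_protein, refs_rna = refs_rna,
                 profiles = profiles, mge_table = mge_table, rules = rules,
                 out_dir = out_dir, require_blast = isTRUE(require_blast),
                 thresholds = thresholds, overrides = over),
            class = "ta_config")
}

#' @rdname ta_config
#' @param path DCF key-value configuration file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  kv <- lapply(kv, as.character)
  defs <- ta_defaults()
  num <- intersect(names(kv), names(defs))
  args <- kv[setdiff(names(kv), num)]
  if ("require_blast" %in% names(args))
    args$require_blast <- toupper(args$require_blast) %in% c("TRUE", "1", "YES")
  for (f in num) args[[f]] <- as.numeric(kv[[f]])
  do.call(ta_config, args)
}

load_genome <- function(config) {
  if (!is.null(config$genome_genbank)) read_genbank(config$genome_genbank)
  else if (!is.null(config$genome_fasta) && !is.null(config$genome_gff))
    read_fasta_gff(config$genome_fasta, config$genome_gff)
  else stop("config needs genome_genbank or genome_fasta + genome_gff")
}

load_refs <- function(config) {
  if (is.null(config$refs_protein) && is.null(config$refs_rna))
    return(bundled_references())
  list(protein = if (!is.null(config$refs_protein))
         read_reference_fasta(config$refs_protein, "protein") else NULL,
       rna = if (!is.null(config$refs_rna))
         read_reference_fasta(config$refs_rna, "rna") else NULL)
}

write_manifest <- function(config, stage, inputs, outputs) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    stage = stage,
    package = "tascan",
    version = as.character(utils::packageVersion("tascan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = config$thresholds,
    threshold_overrides = config$overrides,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs)
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  if (length(config$overrides))
    message("threshold overrides: ",
            paste(names(config$overrides), unlist(config$overrides),
                  sep = "=", collapse = ", "))
  invisible(path)
}

#' Pipeline stages
#'
#' Each stage reads its inputs (the genome, or the previous stage's
#' TSVs under `out_dir`), computes, writes its outputs under `out_dir`,
#' and records a JSON run manifest (package version, thresholds and any
#' overrides, input checksums).
#'
#' \describe{
#'   \item{run_predict}{read genome -> homology searches (+ optional
#'     domain scan) -> candidates -> locus calling -> overlap resolution;
#'     writes `loci.tsv` and `loci.gff3`.}
#'   \item{run_associate}{`loci.tsv` + MGE table -> `links.tsv`.}
#'   \item{run_network}{`links.tsv` + MGE sequences -> MinHash sketches
#'     (`sketches.json`), similarity edges (`similar_edges.tsv`) and the
#'     network files (`nodes.tsv`, `edges.tsv`, `network.json`).}
#'   \item{run_stats}{`loci.tsv` + `links.tsv` + genome -> summary
#'     tables.}
#'   \item{run_simulate}{a plan -> synthetic bundle written to
#'     `out_dir`.}
#' }
#'
#' @param config a [ta_config].
#' @return Each stage returns its main result invisibly (`loci`,
#'   `links`, the network, the summary, or the bundle paths).
#' @export
run_predict <- function(config) {
  genome <- load_genome(config)
  refs <- load_refs(config)
  th <- config$thresholds
  hits <- list()
  if (!is.null(refs$protein) && nrow(refs$protein))
    hits$protein <- search_protein(genome, refs$protein,
                                   evalue_max = th$evalue_blast)
  if (!is.null(refs$rna) && nrow(refs$rna))
    hits$rna <- search_rna(genome, refs$rna, evalue_max = th$evalue_blast)
  hits <- do.call(rbind, hits)
  domain_hits <- if (!is.null(config$profiles))
    scan_domains(genome, config$profiles, evalue_max = th$evalue_hmm)
  else NULL
  cands <- build_candidates(hits, domain_hits, genome,
                            h_cutoff = th$h_value, len_min = th$len_min,
                            len_max = th$len_max,
                            require_blast = config$require_blast)
  rules <- ta_rules(config$rules)
  loci <- resolve_overlaps(call_loci(cands, rules))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "loci.tsv")
  gff <- file.path(config$out_dir, "loci.gff3")
  write_loci_tsv(loci, tsv)
  write_predictions_gff(loci, gff)
  write_manifest(config, "predict",
                 list(genome_genbank = config$genome_genbank,
                      genome_fasta = config$genome_fasta,
                      genome_gff = config$genome_gff,
                      refs_protein = config$refs_protein,
                      refs_rna = config$refs_rna,
                      profiles = config$profiles),
                 list(loci_tsv = tsv, loci_gff = gff))
  invisible(loci)
}

#' @rdname run_predict
#' @export
run_associate <- function(config) {
  if (is.null(config$mge_table)) stop("config needs mge_table")
  loci <- read_loci_tsv(file.path(config$out_dir, "loci.tsv"))
  mges <- read_mge_table(config$mge_table)
  genome <- load_genome(config)
  links <- associate(loci, mges, flank_bp = config$thresholds$flank_bp,
                     replicons = genome$replicons)
  tsv <- file.path(config$out_dir, "links.tsv")
  write_links_tsv(links, tsv)
  write_manifest(config, "associate", list(mge_table = config$mge_table),
                 list(links_tsv = tsv))
  invisible(links)
}

#' @rdname run_predict
#' @export
run_network <- function(config) {
  th <- config$thresholds
  links <- read_links_tsv(file.path(config$out_dir, "links.tsv"))
  genome <- load_genome(config)
  mges <- if (!is.null(config$mge_table)) read_mge_table(config$mge_table)
          else NULL
  sketches <- list()
  if (!is.null(mges) && nrow(mges)) {
    mseq <- mge_sequences(genome, mges, replicons = genome$replicons)
    sketches <- lapply(names(mseq), function(id)
      sketch(mseq[[id]], mge_id = id, k = th$k, s = th$s,
             seed = th$hash_seed))
  }
  sim <- if (length(sketches) >= 2)
    similar_edges(sketches, threshold = th$mash_threshold)
  else data.frame(mge_a = character(), mge_b = character(),
                  distance = numeric(), stringsAsFactors = FALSE)
  net <- build_network(links, sim)
  write_sketches_json(sketches, file.path(config$out_dir, "sketches.json"))
  utils::write.table(sim, file.path(config$out_dir, "similar_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- write_network_files(net, config$out_dir)
  write_manifest(config, "network", list(mge_table = config$mge_table),
                 as.list(paths))
  invisible(net)
}

#' @rdname run_predict
#' @export
run_stats <- function(config) {
  loci <- read_loci_tsv(file.path(config$out_dir, "loci.tsv"))
  links <- read_links_tsv(file.path(config$out_dir, "links.tsv"))
  genome <- load_genome(config)
  summary <- summarize_ta_mge(loci, links, genome)
  paths <- write_summary_files(summary, config$out_dir)
  write_manifest(config, "stats", list(), as.list(paths))
  invisible(summary)
}

#' @rdname run_predict
#' @param plan a [ta_plan]; defaults to [standard_fixture_plan()] seeded
#'   from the config.
#' @export
run_simulate <- function(config, plan = NULL) {
  if (is.null(plan)) plan <- standard_fixture_plan(config$thresholds$seed)
  bundle <- generate_bundle(plan)
  paths <- write_bundle(bundle, config$out_dir)
  write_manifest(config, "simulate", list(), paths)
  invisible(bundle)
}

#' Extract MGE sequences from a genome
#'
#' Returns the nucleotide sequence of each annotated MGE interval (the
#' whole replicon for plasmid-class entries), the input of the MinHash
#' sketching stage. When `replicons` is given, implicit whole-replicon
#' plasmid entries are added as in [associate()].
#'
#' @param genome a [ta_genome].
#' @param mges MGE data.frame (internal coordinates).
#' @param replicons optional replicon table enabling implicit plasmid
#'   MGEs.
#' @return Named character vector of sequences, one per MGE id.
#' @export
mge_sequences <- function(genome, mges, replicons = NULL) {
  mges <- augment_plasmid_mges(mges, replicons)
  out <- character(0)
  for (i in seq_len(NROW(mges))) {
    rid <- mges$replicon_id[i]
    if (!rid %in% names(genome$sequences))
      stop("MGE ", mges$mge_id[i], " on unknown replicon ", rid)
    out[[mges$mge_id[i]]] <- as.character(Biostrings::subseq(
      genome$sequences[[rid]], mges$start[i] + 1L, mges$end[i]))
  }
  out
}
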