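## TA-MGE network construction and summary statistics.
##
## Counting convention: every (locus, MGE) association link is one
## relationship; a locus linked to two MGEs contributes two relationships
## but counts once among "associated loci".

#' Build the TA-MGE network
#'
#' Union graph of typed nodes (TA loci and MGEs) and typed edges
#' (harbored / flanking_IS association links, and MGE-MGE similarity
#' edges). Duplicate edges of the same type between the same pair
#' collapse to one. When `loci` / `mges` tables are supplied, edge
#' endpoints are validated against them and isolated nodes are included.
#'
#' @param links association links from [associate()].
#' @param sim_edges similarity edges from [similar_edges()], or NULL.
#' @param loci,mges optional node tables used for endpoint validation and
#'   isolated nodes.
#' @return An [igraph::igraph] graph; vertex attribute `node_type`
#'   (`ta_locus`/`mge`), edge attributes `edge_type`
#'   (`harbored`/`flanking_IS`/`similar`) and `weight` (gap in bp for
#'   association edges, Mash distance for similarity edges).
#' @export
build_network <- function(links, sim_edges = NULL, loci = NULL, mges = NULL) {
  links <- if (NROW(links)) unique(links[, c("locus_id", "mge_id",
                                             "link_kind", "gap")])
           else NULL
  sim <- if (NROW(sim_edges)) unique(sim_edges[, c("mge_a", "mge_b",
                                                   "distance")])
         else NULL
  locus_nodes <- unique(c(if (!is.null(links)) links$locus_id,
                          if (!is.null(loci)) loci$locus_id))
  mge_nodes <- unique(c(if (!is.null(links)) links$mge_id,
                        if (!is.null(sim)) c(sim$mge_a, sim$mge_b),
                        if (!is.null(mges)) mges$mge_id))
  if (!is.null(loci)) {
    dangling <- setdiff(if (!is.null(links)) links$locus_id else character(),
                        loci$locus_id)
    if (length(dangling))
      stop("links reference unknown locus id(s): ",
           paste(dangling, collapse = ", "))
  }
  if (!is.null(mges)) {
    used <- c(if (!is.null(links)) links$mge_id,
              if (!is.null(sim)) c(sim$mge_a, sim$mge_b))
    dangling <- setdiff(used, mges$mge_id)
    if (length(dangling))
      stop("edges reference unknown MGE id(s): ",
           paste(dangling, collapse = ", "))
  }
  nodes <- data.frame(
    name = c(locus_nodes, mge_nodes),
    node_type = c(rep("ta_locus", length(locus_nodes)),
                  rep("mge", length(mge_nodes))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    if (!is.null(links)) data.frame(from = links$locus_id,
                                    to = links$mge_id,
                                    edge_type = links$link_kind,
                                    weight = as.numeric(links$gap),
                                    stringsAsFactors = FALSE),
    if (!is.null(sim)) data.frame(from = sim$mge_a, to = sim$mge_b,
                                  edge_type = "similar",
                                  weight = sim$distance,
                                  stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        edge_type = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Per-locus subnetwork
#'
#' The connected component of the network containing the given locus --
#' the locus, its associated MGEs, those MGEs' similar MGEs, and any
#' further loci they reach.
#'
#' @param network graph from [build_network()].
#' @param locus_id the TA locus of interest.
#' @return The induced subgraph of the component.
#' @export
locus_subnetwork <- function(network, locus_id) {
  if (!locus_id %in% igraph::V(network)$name)
    stop("unknown locus id: ", locus_id)
  comp <- igraph::components(network)
  keep <- comp$membership == comp$membership[[locus_id]]
  igraph::induced_subgraph(network, igraph::V(network)[keep])
}

#' Summary statistics of TA loci and their MGE associations
#'
#' Reproduces, at the scale of the supplied inputs, the summary tables of
#' a TA-MGE survey: loci per TA type; relationship counts per TA type x
#' MGE class and per family x MGE class (each link counted separately);
#' per-species strain counts and mean loci per strain (species = first
#' two whitespace tokens of the organism string); and headline
#' proportions (fraction of loci with at least one link, fraction of
#' plasmid replicons carrying at least one locus), as percentages to one
#' decimal.
#'
#' @param loci locus data.frame.
#' @param links link data.frame from [associate()].
#' @param genomes a [ta_genome] or list of them (one per strain).
#' @return List of class `ta_summary`: `per_type_counts`,
#'   `association_matrix`, `family_matrix`, `per_species`, `proportions`.
#' @export
summarize_ta_mge <- function(loci, links, genomes) {
  if (inherits(genomes, "ta_genome")) genomes <- list(genomes)
  per_type <- data.frame(ta_type = ROMAN_TYPES,
                         n_loci = vapply(ROMAN_TYPES, function(tt)
                           sum(loci$ta_type == tt), integer(1)),
                         row.names = NULL, stringsAsFactors = FALSE)

  classes <- MGE_CLASSES
  xmat <- function(row_values, all_rows) {
    m <- matrix(0L, nrow = length(all_rows), ncol = length(classes),
                dimnames = list(all_rows, classes))
    if (NROW(links)) {
      li <- match(links$locus_id, loci$locus_id)
      rv <- row_values[li]
      for (i in seq_len(nrow(links)))
        if (!is.na(rv[i]))
          m[rv[i], links$mge_class[i]] <- m[rv[i], links$mge_class[i]] + 1L
    }
    m
  }
  assoc <- xmat(loci$ta_type, ROMAN_TYPES)
  fams <- sort(unique(loci$family))
  fam <- if (length(fams)) xmat(loci$family, fams)
         else matrix(0L, 0, length(classes),
                     dimnames = list(NULL, classes))

  species_of <- function(org) {
    toks <- strsplit(trimws(org), "\\s+")[[1]]
    paste(toks[seq_len(min(2, length(toks)))], collapse = " ")
  }
  strain_rows <- lapply(genomes, function(g) {
    sp <- species_of(g$replicons$organism[1])
    n <- sum(loci$replicon_id %in% g$replicons$id)
    data.frame(species = sp, n_loci = n, stringsAsFactors = FALSE)
  })
  strains <- do.call(rbind, strain_rows)
  per_species <- do.call(rbind, lapply(split(strains, strains$species),
    function(d) data.frame(species = d$species[1], n_strains = nrow(d),
                           n_loci = sum(d$n_loci),
                           mean_loci_per_strain = round(mean(d$n_loci), 1),
                           stringsAsFactors = FALSE)))
  per_species <- per_species[order(per_species$species), , drop = FALSE]
  rownames(per_species) <- NULL

  total_loci <- NROW(loci)
  associated <- length(unique(links$locus_id[links$locus_id %in%
                                               loci$locus_id]))
  all_reps <- do.call(rbind, lapply(genomes, `[[`, "replicons"))
  plasmids <- all_reps$id[all_reps$kind == "plasmid"]
  plasmids_with <- sum(vapply(plasmids, function(p)
    any(loci$replicon_id == p), logical(1)))
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  proportions <- list(
    total_loci = total_loci,
    relationships = NROW(links),
    associated_loci = associated,
    associated_loci_pct = pct(associated, total_loci),
    plasmids_total = length(plasmids),
    plasmids_with_locus = plasmids_with,
    plasmids_with_locus_pct = pct(plasmids_with, length(plasmids)))

  structure(list(per_type_counts = per_type, association_matrix = assoc,
                 family_matrix = fam, per_species = per_species,
                 proportions = proportions),
            class = "ta_summary")
}

#' @export
print.ta_summary <- function(x, ...) {
  p <- x$proportions
  cat(sprintf(
    "TA loci: %d total; %d associated with MGEs (%s%%) via %d relationships\n",
    p$total_loci, p$associated_loci,
    format(p$associated_loci_pct), p$relationships))
  if (p$plasmids_total > 0)
    cat(sprintf("plasmids with >=1 locus: %d/%d (%s%%)\n",
                p$plasmids_with_locus, p$plasmids_total,
                format(p$plasmids_with_locus_pct)))
  cat("loci per type: ",
      paste(sprintf("%s=%d", x$per_type_counts$ta_type,
                    x$per_type_counts$n_loci), collapse = " "), "\n")
  invisible(x)
}

#' Export the network and summary tables
#'
#' Writes node and edge TSVs plus one JSON graph file (`nodes`, `edges`
#' arrays), and the summary tables as TSVs into a directory.
#'
#' @param network graph from [build_network()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_network_files <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(name = igraph::V(network)$name,
                      node_type = igraph::V(network)$node_type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(network)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      edge_type = igraph::E(network)$edge_type %||% character(),
                      weight = igraph::E(network)$weight %||% numeric(),
                      stringsAsFactors = FALSE)
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  jp <- file.path(dir, "network.json")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(nodes = nodes, edges = edges), jp,
                       dataframe = "rows")
  invisible(c(np, ep, jp))
}

#' @rdname write_network_files
#' @param summary a `ta_summary` from [summarize_ta_mge()].
#' @export
write_summary_files <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  paths <- c(
    w(summary$per_type_counts, "per_type_counts.tsv"),
    w(cbind(ta_type = rownames(summary$association_matrix),
            as.data.frame(summary$association_matrix)),
      "association_matrix.tsv"),
    w(cbind(family = rownames(summary$family_matrix),
            as.data.frame(summary$family_matrix)), "family_matrix.tsv"),
    w(summary$per_species, "per_species.tsv"),
    w(as.data.frame(summary$proportions), "proportions.tsv"))
  invisible(paths)
}
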