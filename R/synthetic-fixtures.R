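# Fixture generator for the network-integration stage: miRNA->target tables
# with planted k-way sharing, protein-interaction edge lists with planted hub
# cliques, and drug-gene tables. Stands in structurally for target-prediction,
# interaction and drug-database extracts.

#' Plan the planted structure of network fixtures
#'
#' @param mirnas Character vector of miRNA names.
#' @param gene_universe Pool of gene symbols for filler targets.
#' @param planted_shared Named list mapping the sharing level `k` (as a name,
#'   e.g. `"5"`) to genes that must appear in exactly `k` target lists.
#' @param planted_hub_cliques List of `list(mirna =, genes =)` entries; the
#'   genes become targets of that miRNA and a clique in the PPI graph. A gene
#'   may appear in cliques of several miRNAs (a hub shared between miRNAs)
#'   but must not collide with `planted_shared` genes.
#' @param drug_rows data.frame with columns `drug`, `gene` (may be empty).
#' @param n_filler_targets Unique filler targets per miRNA (each targeted by
#'   exactly one miRNA).
#' @param ppi_extra_edges Random sparse edges added between non-clique genes.
#' @return A validated plan list.
#' @export
fixture_plan <- function(mirnas, gene_universe, planted_shared = list(),
                         planted_hub_cliques = list(),
                         drug_rows = data.frame(drug = character(),
                                                gene = character()),
                         n_filler_targets = 20L, ppi_extra_edges = 30L) {
  stopifnot(length(mirnas) >= 1L, !anyDuplicated(mirnas))
  shared_genes <- unlist(planted_shared, use.names = FALSE)
  if (anyDuplicated(shared_genes)) {
    stopf("planted gene collision: a gene may sit in only one sharing stratum")
  }
  if (length(planted_shared)) {
    ks <- as.integer(names(planted_shared))
    if (anyNA(ks) || any(ks < 1L) || any(ks > length(mirnas))) {
      stopf("planted_shared names must be integers in 1..length(mirnas)")
    }
  }
  clique_genes <- unique(unlist(lapply(planted_hub_cliques, `[[`, "genes")))
  if (length(intersect(clique_genes, shared_genes))) {
    stopf("planted gene collision between hub cliques and shared strata")
  }
  for (cl in planted_hub_cliques) {
    if (is.null(cl$mirna) || !cl$mirna %in% mirnas) {
      stopf("every planted clique needs a 'mirna' drawn from 'mirnas'")
    }
    if (length(cl$genes) < 2L || anyDuplicated(cl$genes)) {
      stopf("planted cliques need >= 2 distinct genes")
    }
  }
  stopifnot(is.data.frame(drug_rows),
            all(c("drug", "gene") %in% names(drug_rows)))
  need_fill <- length(mirnas) * n_filler_targets
  pool <- setdiff(gene_universe, c(shared_genes, clique_genes))
  if (length(pool) < need_fill) {
    stopf("gene_universe too small: need %d filler genes, have %d",
          need_fill, length(pool))
  }
  list(mirnas = mirnas, gene_universe = gene_universe,
       planted_shared = planted_shared,
       planted_hub_cliques = planted_hub_cliques, drug_rows = drug_rows,
       n_filler_targets = as.integer(n_filler_targets),
       ppi_extra_edges = as.integer(ppi_extra_edges))
}

#' Generate target/PPI/drug fixture tables with planted structure
#'
#' The emitted target table realizes `planted_shared` exactly (each stratum
#' gene is assigned to exactly `k` randomly chosen miRNAs) plus per-miRNA
#' unique filler targets; the PPI edge list contains each planted clique
#' fully connected plus sparse random edges among non-clique genes; the drug
#' table realizes `drug_rows` verbatim.
#'
#' @param plan A [fixture_plan()].
#' @param seed Integer seed.
#' @return A list with data.frames `targets` (`mirna`, `gene`, `evidence`),
#'   `ppi` (`gene_a`, `gene_b`) and `drugs` (`drug`, `gene`).
#' @export
generate_fixtures <- function(plan, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (kname in names(plan$planted_shared)) {
      k <- as.integer(kname)
      for (g in plan$planted_shared[[kname]]) {
        picked <- sample(plan$mirnas, k)
        rows[[length(rows) + 1L]] <-
          data.frame(mirna = picked, gene = g, stringsAsFactors = FALSE)
      }
    }
    for (cl in plan$planted_hub_cliques) {
      rows[[length(rows) + 1L]] <-
        data.frame(mirna = cl$mirna, gene = cl$genes, stringsAsFactors = FALSE)
    }
    clique_genes <- unique(unlist(lapply(plan$planted_hub_cliques,
                                         `[[`, "genes")))
    shared_genes <- unlist(plan$planted_shared, use.names = FALSE)
    pool <- setdiff(plan$gene_universe, c(shared_genes, clique_genes))
    fill <- sample(pool, length(plan$mirnas) * plan$n_filler_targets)
    if (length(fill)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = rep(plan$mirnas, each = plan$n_filler_targets),
        gene = fill, stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, rows)
    targets <- targets[!duplicated(targets[c("mirna", "gene")]), ]
    targets$evidence <- sample(c("predicted", "weak_validated",
                                 "strong_validated"),
                               nrow(targets), replace = TRUE,
                               prob = c(0.7, 0.2, 0.1))
    rownames(targets) <- NULL

    edges <- list()
    for (cl in plan$planted_hub_cliques) {
      pairs <- utils::combn(sort(cl$genes), 2L)
      edges[[length(edges) + 1L]] <-
        data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                   stringsAsFactors = FALSE)
    }
    non_clique <- setdiff(unique(targets$gene), clique_genes)
    if (plan$ppi_extra_edges > 0L && length(non_clique) >= 2L) {
      # Sparse filler edges form a partial matching among non-clique genes:
      # every non-clique node keeps MCC <= 1 (one maximal 2-clique), so the
      # planted cliques are guaranteed to out-score them and the planted
      # structure stays exactly recoverable.
      pool <- sample(non_clique)
      n_pairs <- min(plan$ppi_extra_edges, floor(length(pool) / 2))
      if (n_pairs > 0L) {
        a <- pool[seq_len(n_pairs) * 2 - 1]
        b <- pool[seq_len(n_pairs) * 2]
        edges[[length(edges) + 1L]] <-
          data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                     stringsAsFactors = FALSE)
      }
    }
    ppi <- if (length(edges)) do.call(rbind, edges) else
      data.frame(gene_a = character(), gene_b = character())
    ppi <- ppi[!duplicated(ppi), ]
    rownames(ppi) <- NULL

    drugs <- plan$drug_rows[, c("drug", "gene"), drop = FALSE]
    rownames(drugs) <- NULL
    list(targets = targets, ppi = ppi, drugs = drugs)
  })
}

#' Write fixture tables as TSV files
#'
#' @param fixtures Result of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(targets = file.path(dir, "targets.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             drugs = file.path(dir, "drugs.tsv"))
  for (nm in names(paths)) {
    utils::write.table(fixtures[[nm]], paths[[nm]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
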