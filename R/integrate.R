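# Integration of screen hits with expression candidates: k-way shared
# predicted targets, maximal clique centrality (MCC) hub scoring on
# protein-interaction graphs, merged network assembly, and drug-gene joins.

#' Normalize miRNA names
#'
#' Strips a species prefix (e.g. `hsa-`) and canonicalizes the `miR`
#' capitalization, while preserving arm suffixes (-3p/-5p).
#'
#' @param x Character vector of miRNA names.
#' @return Normalized names.
#' @export
normalize_mirna <- function(x) {
  y <- trimws(as.character(x))
  y <- sub("^[A-Za-z]{3,4}-(?=(mir|let))", "", y, perl = TRUE,
           ignore.case = TRUE)
  y <- sub("^mir(?=-)", "miR", y, perl = TRUE, ignore.case = TRUE)
  y
}

#' Intersect screen hits with up-regulated miRNAs
#'
#' Both lists are name-normalized first. If one list carries -3p/-5p arm
#' annotation and the other carries none at all, the naming schemes cannot
#' be matched reliably and an explicit error is raised (never silent partial
#' matching). The intersection keeps the screen's rank order.
#'
#' @param screen_hits Character vector of contractile screen hits, ranked.
#' @param de_up Character vector of up-regulated miRNAs.
#' @return The overlapping miRNAs in screen order, with a `venn` attribute
#'   `c(n_screen, n_de, n_overlap)`. Warns when the overlap is empty.
#' @export
intersect_candidates <- function(screen_hits, de_up) {
  a <- normalize_mirna(screen_hits)
  b <- normalize_mirna(de_up)
  has_arm <- function(v) grepl("-(3|5)p$", v)
  if (length(a) && length(b)) {
    if ((all(has_arm(a)) && !any(has_arm(b))) ||
        (all(has_arm(b)) && !any(has_arm(a)))) {
      stopf(paste("miRNA naming schemes differ in arm annotation (-3p/-5p);",
                  "resolve with an explicit mapping before intersecting"))
    }
  }
  overlap <- a[a %in% b]
  overlap <- overlap[!duplicated(overlap)]
  if (!length(overlap)) warnf("no overlap between screen hits and DE miRNAs")
  structure(overlap,
            venn = c(n_screen = length(unique(a)), n_de = length(unique(b)),
                     n_overlap = length(overlap)))
}

#' Group target genes by how many miRNAs predict them
#'
#' @param targets Target table with columns `mirna`, `gene` (duplicate
#'   pairs are dropped with a warning).
#' @param k_min Keep genes targeted by at least `k_min` distinct miRNAs.
#' @return data.frame `gene`, `k`, `mirnas` (comma-joined, sorted), ordered
#'   by decreasing `k`; the `k_counts` attribute tabulates all genes (so the
#'   counts over strata sum to the number of distinct genes in the table).
#' @export
shared_targets <- function(targets, k_min = 1L) {
  stopifnot(all(c("mirna", "gene") %in% names(targets)))
  if (k_min < 1L) stopf("k_min must be >= 1")
  dup <- duplicated(targets[c("mirna", "gene")])
  if (any(dup)) {
    warnf("%d duplicate (mirna, gene) pairs dropped", sum(dup))
    targets <- targets[!dup, ]
  }
  by_gene <- split(targets$mirna, targets$gene)
  k <- vapply(by_gene, function(m) length(unique(m)), integer(1))
  res <- data.frame(gene = names(by_gene), k = k,
                    mirnas = vapply(by_gene, function(m) {
                      paste(sort(unique(m)), collapse = ",")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  k_counts <- table(factor(res$k, levels = seq_len(max(res$k))))
  res <- res[res$k >= k_min, ]
  res <- res[order(-res$k, res$gene), ]
  rownames(res) <- NULL
  attr(res, "k_counts") <- k_counts
  res
}

# --- graph plumbing ---------------------------------------------------------

as_adjacency <- function(graph, nodes = NULL) {
  if (inherits(graph, "igraph")) {
    if (!igraph::is_simple(graph)) {
      stopf("graph must be simple (no self-loops or multi-edges)")
    }
    el <- igraph::as_edgelist(graph, names = TRUE)
    vs <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
    edges <- data.frame(gene_a = as.character(el[, 1]),
                        gene_b = as.character(el[, 2]),
                        stringsAsFactors = FALSE)
  } else if (is.data.frame(graph)) {
    if (ncol(graph) < 2L) stopf("edge list needs two columns")
    edges <- data.frame(gene_a = as.character(graph[[1]]),
                        gene_b = as.character(graph[[2]]),
                        stringsAsFactors = FALSE)
    if (any(edges$gene_a == edges$gene_b)) {
      stopf("graph must be simple (no self-loops or multi-edges)")
    }
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    if (anyDuplicated(key)) {
      stopf("graph must be simple (no self-loops or multi-edges)")
    }
    vs <- unique(c(edges$gene_a, edges$gene_b))
  } else {
    stopf("graph must be an igraph object or an edge-list data.frame")
  }
  vs <- unique(c(vs, nodes))
  adj <- lapply(stats::setNames(vector("list", length(vs)), vs),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Bron-Kerbosch with pivoting on integer node indices. Returns a list of
# maximal cliques (integer vectors), size >= 2 only.
bron_kerbosch <- function(adj_idx, budget = 1e5) {
  cliques <- vector("list", 0L)
  n_found <- 0L
  recurse <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      if (length(r) >= 2L) {
        n_found <<- n_found + 1L
        if (n_found > budget) {
          stopf(paste("maximal clique enumeration exceeded the budget of",
                      budget, "cliques; extract a subgraph first"))
        }
        cliques[[n_found]] <<- r
      }
      return(invisible())
    }
    pool <- c(p, x)
    deg <- vapply(pool, function(u) length(intersect(adj_idx[[u]], p)),
                  integer(1))
    pivot <- pool[which.max(deg)]
    for (v in setdiff(p, adj_idx[[pivot]])) {
      recurse(c(r, v), intersect(p, adj_idx[[v]]), intersect(x, adj_idx[[v]]))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  recurse(integer(0), seq_along(adj_idx), integer(0))
  cliques
}

#' Maximal clique centrality (MCC) scores
#'
#' Enumerates all maximal cliques (Bron-Kerbosch with pivoting) and scores
#' each node by `sum((|C| - 1)!)` over the maximal cliques `C` of size >= 2
#' that contain it. Isolated nodes score 0.
#'
#' @param graph igraph object or two-column edge-list data.frame (simple,
#'   undirected).
#' @param nodes Extra node names to include as isolated vertices (edge lists
#'   cannot carry them).
#' @param clique_budget Abort with an error when more maximal cliques than
#'   this are found.
#' @return Named numeric vector of MCC scores over all nodes.
#' @export
mcc_scores <- function(graph, nodes = NULL, clique_budget = 1e5) {
  adj <- as_adjacency(graph, nodes)
  vs <- names(adj)
  adj_idx <- lapply(adj, function(nb) sort(match(nb, vs)))
  cliques <- bron_kerbosch(adj_idx, budget = clique_budget)
  mcc <- stats::setNames(numeric(length(vs)), vs)
  for (cl in cliques) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }
  mcc
}

#' Select top hub target genes per miRNA
#'
#' For each miRNA the MCC is computed on the subgraph induced by that
#' miRNA's own targets (mirroring per-miRNA interaction analysis; a global
#' mode scores on the full graph instead). Targets absent from the graph
#' count as isolated (MCC 0). Ranking: MCC desc, degree desc, then
#' lexicographic; the top `per_mirna_top` genes per miRNA are flagged and
#' their deduplicated union forms the hub set.
#'
#' @param targets Target table (`mirna`, `gene`).
#' @param graph PPI graph (igraph or edge-list data.frame).
#' @param per_mirna_top Hubs per miRNA (default 3).
#' @param mode `"induced"` (default) or `"global"` MCC scoring.
#' @param clique_budget Passed to [mcc_scores()].
#' @return A list of class `hub_network`: `per_mirna` (named list of hub
#'   gene vectors), `hub_set` (sorted union), `scores` (per miRNA-gene MCC,
#'   degree, rank, hub flag).
#' @export
select_hubs <- function(targets, graph, per_mirna_top = 3L,
                        mode = c("induced", "global"), clique_budget = 1e5) {
  mode <- match.arg(mode)
  stopifnot(all(c("mirna", "gene") %in% names(targets)))
  adj_all <- as_adjacency(graph, nodes = unique(targets$gene))
  global_mcc <- if (mode == "global") {
    mcc_scores(graph, nodes = unique(targets$gene),
               clique_budget = clique_budget)
  } else NULL
  per_mirna <- list()
  scores <- list()
  for (m in unique(targets$mirna)) {
    genes <- sort(unique(targets$gene[targets$mirna == m]))
    if (mode == "induced") {
      sub_edges <- induced_edges(adj_all, genes)
      mcc <- if (nrow(sub_edges)) {
        mcc_scores(sub_edges, nodes = genes, clique_budget = clique_budget)
      } else {
        stats::setNames(numeric(length(genes)), genes)
      }
      deg <- vapply(genes, function(g) {
        length(intersect(adj_all[[g]], genes))
      }, integer(1))
    } else {
      mcc <- global_mcc[genes]
      deg <- vapply(genes, function(g) length(adj_all[[g]]), integer(1))
    }
    if (length(genes) < per_mirna_top) {
      warnf("miRNA %s has only %d target(s); taking all as hubs",
            m, length(genes))
    }
    ord <- order(-mcc[genes], -deg, genes)
    top <- genes[ord][seq_len(min(per_mirna_top, length(genes)))]
    per_mirna[[m]] <- top
    scores[[m]] <- data.frame(mirna = m, gene = genes[ord],
                              mcc = as.numeric(mcc[genes][ord]),
                              degree = as.integer(deg[ord]),
                              rank = seq_along(genes),
                              hub = genes[ord] %in% top,
                              stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  structure(list(per_mirna = per_mirna,
                 hub_set = sort(unique(unlist(per_mirna))),
                 scores = scores),
            class = "hub_network")
}

induced_edges <- function(adj, genes) {
  rows <- list()
  gset <- genes
  for (g in intersect(names(adj), gset)) {
    nb <- intersect(adj[[g]], gset)
    nb <- nb[nb > g]  # each undirected edge once
    if (length(nb)) {
      rows[[length(rows) + 1L]] <- data.frame(gene_a = g, gene_b = nb,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character())
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf("Hub network: %d miRNAs, hub set of %d genes\n",
              length(x$per_mirna), length(x$hub_set)))
  invisible(x)
}

#' Assemble the merged shared-target / hub network
#'
#' Nodes are the shared targets at `k >= k_min` plus the hub set; each node
#' is annotated with its role (shared/hub/both), sharing level `k`,
#' targeting miRNAs and MCC score; edges are the PPI edges induced on the
#' node set.
#'
#' @param shared [shared_targets()] result.
#' @param hubs [select_hubs()] result.
#' @param graph PPI graph (igraph or edge-list data.frame).
#' @param k_min Sharing stratum cutoff for node inclusion (default 4).
#' @return A list with `nodes` and `edges` data.frames.
#' @export
build_network <- function(shared, hubs, graph, k_min = 4L) {
  sh <- shared[shared$k >= k_min, , drop = FALSE]
  node_names <- union(sh$gene, hubs$hub_set)
  role <- ifelse(node_names %in% sh$gene & node_names %in% hubs$hub_set,
                 "both",
                 ifelse(node_names %in% sh$gene, "shared", "hub"))
  k <- sh$k[match(node_names, sh$gene)]
  mirnas <- sh$mirnas[match(node_names, sh$gene)]
  hub_for <- vapply(node_names, function(g) {
    paste(names(hubs$per_mirna)[vapply(hubs$per_mirna, function(v) g %in% v,
                                       logical(1))], collapse = ",")
  }, character(1))
  mcc <- vapply(node_names, function(g) {
    s <- hubs$scores$mcc[hubs$scores$gene == g]
    if (length(s)) max(s) else 0
  }, numeric(1))
  nodes <- data.frame(gene = node_names, role = role, k = k,
                      mirnas = mirnas, hub_for = hub_for, mcc = mcc,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), ]
  rownames(nodes) <- NULL
  adj <- as_adjacency(graph, nodes = node_names)
  edges <- induced_edges(adj, node_names)
  list(nodes = nodes, edges = edges)
}

#' Export a merged network as GraphML and edge-list TSV
#'
#' @param network [build_network()] result.
#' @param graphml_path,edges_path Output paths (`NULL` to skip either).
#' @return Invisibly, the igraph object.
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(g)
}

#' Join network genes with drug-gene interactions
#'
#' Inner join of the genes with the drug table, expanded to
#' (miRNA, gene, drug) triples through the target table. Coverage is the
#' fraction of `coverage_genes` (default: all supplied genes) linked to at
#' least one drug.
#'
#' @param genes Character vector of network genes.
#' @param drug_table data.frame with columns `drug`, `gene`.
#' @param targets Target table (`mirna`, `gene`) used to attribute genes to
#'   miRNAs.
#' @param coverage_genes Genes over which coverage is computed (e.g. the hub
#'   set).
#' @return A list: `triples` (data.frame `mirna`, `gene`, `drug`),
#'   `coverage` (fraction), `n_druggable`, `n_genes`.
#' @export
map_drugs <- function(genes, drug_table, targets, coverage_genes = genes) {
  stopifnot(all(c("drug", "gene") %in% names(drug_table)),
            all(c("mirna", "gene") %in% names(targets)))
  genes <- unique(genes)
  rows <- list()
  for (g in genes) {
    drugs <- unique(drug_table$drug[drug_table$gene == g])
    if (!length(drugs)) next
    mirnas <- unique(targets$mirna[targets$gene == g])
    if (!length(mirnas)) mirnas <- NA_character_
    rows[[length(rows) + 1L]] <- expand.grid(mirna = mirnas, gene = g,
                                             drug = drugs,
                                             stringsAsFactors = FALSE)
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene = character(), drug = character())
  triples <- triples[order(triples$mirna, triples$gene, triples$drug), ]
  rownames(triples) <- NULL
  druggable <- unique(triples$gene)
  n_cov <- sum(coverage_genes %in% drug_table$gene)
  list(triples = triples,
       coverage = if (length(coverage_genes)) {
         n_cov / length(coverage_genes)
       } else 0,
       n_druggable = n_cov, n_genes = length(coverage_genes))
}
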