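# End-to-end orchestration: simulate -> segment -> screen -> de -> integrate,
# driven by a single config and a root seed, writing TSV artifacts with
# provenance headers.

#' Default pipeline configuration
#'
#' A small self-contained demonstration setup: a roster of miRNA conditions
#' screened on a 3-replicate plate, a count matrix whose first rows carry
#' the same names (a subset planted as up-regulated AND screened at a high
#' contractile fraction, so the intersection is non-trivial), and network
#' fixtures built over the overlap candidates.
#'
#' @param seed Root seed; every stage derives its own child seed from it.
#' @return A nested configuration list (YAML/JSON-serializable).
#' @export
default_config <- function(seed = 1L) {
  roster <- c("miR-132-3p", "miR-138-5p", "miR-141-3p", "miR-145-5p",
              "miR-150-5p", "miR-22-3p", "miR-330-5p", "miR-99b-5p")
  active <- roster[1:6]   # high contractile fraction + planted up-regulation
  list(
    seed = seed,
    mirnas = roster,
    active_mirnas = active,
    plate = list(n_cells = 150L, control_fraction = 0.2,
                 active_fraction = 0.6, inactive_fraction = 0.2,
                 render_wells = 1L, image_size = 640L, noise_sd = 0.02),
    counts = list(n_mirnas = 300L, n_per_group = 4L, nb_dispersion = 0.1,
                  effect_log2fc = 2.5),
    de = list(lfc_threshold = 0.6, alpha = 0.05, use_fdr = TRUE),
    screen = list(strong_fc = 1.5, weak_fc = 1.2),
    network = list(k_min = 4L, per_mirna_top = 3L,
                   n_genes = 400L, n_filler_targets = 15L,
                   ppi_extra_edges = 25L)
  )
}

write_tsv <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# vsmcscreen %s", as.character(utils::packageVersion("vsmcscreen"))),
    sprintf("# config-hash: %s", config_hash),
    sprintf("# seed: %s", seed)
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic inputs and
#' writes TSV artifacts into `outdir`. Later stages read the artifacts of
#' earlier ones, so a missing upstream file produces an error naming the
#' stage that creates it. Reruns with the same config and seed produce
#' byte-identical TSV outputs.
#'
#' @param stages Character vector from `simulate`, `segment`, `screen`,
#'   `de`, `integrate`, or `"all"`.
#' @param config Configuration list (see [default_config()]) or a path to a
#'   YAML/JSON file with the same structure.
#' @param outdir Output directory.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a named vector of artifact paths.
#' @export
run_pipeline <- function(stages = "all", config = default_config(),
                         outdir = "vsmcscreen_out", seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.null(seed)) config$seed <- seed
  base <- default_config(seed = config$seed %||% 1L)
  config <- utils::modifyList(base, config)
  all_stages <- c("simulate", "segment", "screen", "de", "integrate")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    stopf("unknown stage(s): %s (choose from %s or 'all')",
          paste(unknown, collapse = ", "), paste(all_stages, collapse = ", "))
  }
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a(paste(deparse(config), collapse = ""))
  seed <- config$seed
  p <- function(...) file.path(outdir, paste0(...))
  need <- function(path, producer) {
    if (!file.exists(path)) {
      stopf("missing artifact %s; run the '%s' stage first", path, producer)
    }
    path
  }
  artifacts <- c()

  if ("simulate" %in% stages) {
    message("[simulate] plate, counts and network fixtures")
    sim <- simulate_stage(config)
    write_tsv(sim$plate_truth, p("plate_truth.tsv"), hash, seed)
    write_tsv(sim$design, p("plate_design.tsv"), hash, seed)
    write_tsv(data.frame(mirna = rownames(sim$counts$counts),
                         sim$counts$counts, check.names = FALSE),
              p("counts.tsv"), hash, seed)
    write_tsv(data.frame(sample_id = names(sim$counts$groups),
                         group = as.character(sim$counts$groups)),
              p("samples.tsv"), hash, seed)
    write_tsv(sim$counts$truth, p("counts_truth.tsv"), hash, seed)
    write_tsv(sim$fixtures$targets, p("targets.tsv"), hash, seed)
    write_tsv(sim$fixtures$ppi, p("ppi.tsv"), hash, seed)
    write_tsv(sim$fixtures$drugs, p("drugs.tsv"), hash, seed)
    if (length(sim$images)) {
      for (nm in names(sim$images)) {
        EBImage::writeImage(EBImage::Image(sim$images[[nm]]),
                            p("well_", nm, ".tif"), type = "tiff",
                            bits.per.sample = 16L)
      }
    }
    artifacts <- c(artifacts, plate_truth = p("plate_truth.tsv"),
                   counts = p("counts.tsv"), targets = p("targets.tsv"))
  }

  if ("segment" %in% stages) {
    tifs <- list.files(outdir, pattern = "^well_.*\\.tif$", full.names = TRUE)
    if (!length(tifs)) {
      stopf("no rendered well images in %s; run the 'simulate' stage first",
            outdir)
    }
    message(sprintf("[segment] %d rendered well(s)", length(tifs)))
    recs <- lapply(tifs, function(f) {
      img <- EBImage::readImage(f)
      arr <- array(as.numeric(img), dim = dim(img))
      mask <- segment_cells(arr)
      wid <- sub("^well_(.*)\\.tif$", "\\1", basename(f))
      classify_phenotype(measure_shape(mask, arr[, , 2], well_id = wid))
    })
    write_tsv(do.call(rbind, recs), p("cell_records.tsv"), hash, seed)
    artifacts <- c(artifacts, cell_records = p("cell_records.tsv"))
  }

  if ("screen" %in% stages) {
    message("[screen] well summaries, fold changes and hit calls")
    truth <- read_tsv(need(p("plate_truth.tsv"), "simulate"))
    design <- read_tsv(need(p("plate_design.tsv"), "simulate"))
    summaries <- do.call(rbind, lapply(split(truth, truth$well_id),
                                       function(tw) {
      summarize_well(classify_phenotype(truth_records(tw)))
    }))
    scr <- screen_table(summaries, design,
                        strong_fc = config$screen$strong_fc,
                        weak_fc = config$screen$weak_fc)
    write_tsv(scr$conditions, p("screen_conditions.tsv"), hash, seed)
    write_tsv(scr$wells, p("screen_wells.tsv"), hash, seed)
    hits <- scr$conditions$condition_label[
      scr$conditions$category %in% c("strong_contractile", "weak_contractile")]
    writeLines(hits, p("screen_hits.txt"))
    message(sprintf("[screen] %d condition(s), %d contractile hit(s)",
                    nrow(scr$conditions), length(hits)))
    artifacts <- c(artifacts, screen_conditions = p("screen_conditions.tsv"),
                   screen_hits = p("screen_hits.txt"))
  }

  if ("de" %in% stages) {
    message("[de] logCPM + moderated t")
    ctab <- read_tsv(need(p("counts.tsv"), "simulate"))
    counts <- as.matrix(ctab[, -1])
    rownames(counts) <- ctab$mirna
    samples <- read_tsv(need(p("samples.tsv"), "simulate"))
    groups <- stats::setNames(samples$group, samples$sample_id)
    fit <- fit_moderated(logcpm(counts), groups[colnames(counts)])
    res <- call_de(fit, lfc_threshold = config$de$lfc_threshold,
                   alpha = config$de$alpha, use_fdr = config$de$use_fdr)
    write_tsv(res, p("de_results.tsv"), hash, seed)
    writeLines(res$mirna[res$call == "up"], p("de_up.txt"))
    writeLines(res$mirna[res$call == "down"], p("de_down.txt"))
    message(sprintf("[de] %d up / %d down of %d miRNAs",
                    sum(res$call == "up"), sum(res$call == "down"),
                    nrow(res)))
    artifacts <- c(artifacts, de_results = p("de_results.tsv"),
                   de_up = p("de_up.txt"))
  }

  if ("integrate" %in% stages) {
    message("[integrate] candidate overlap, shared targets, hubs, drugs")
    hits <- readLines(need(p("screen_hits.txt"), "screen"))
    de_up <- readLines(need(p("de_up.txt"), "de"))
    candidates <- intersect_candidates(hits, de_up)
    writeLines(candidates, p("candidates.txt"))
    targets <- read_tsv(need(p("targets.tsv"), "simulate"))
    ppi <- read_tsv(need(p("ppi.tsv"), "simulate"))
    drugs <- read_tsv(need(p("drugs.tsv"), "simulate"))
    targets <- targets[normalize_mirna(targets$mirna) %in% candidates, ]
    shared <- shared_targets(targets)
    hubs <- select_hubs(targets, ppi,
                        per_mirna_top = config$network$per_mirna_top)
    net <- build_network(shared, hubs, ppi, k_min = config$network$k_min)
    drug_map <- map_drugs(net$nodes$gene, drugs, targets,
                          coverage_genes = hubs$hub_set)
    write_tsv(shared, p("shared_targets.tsv"), hash, seed)
    write_tsv(hubs$scores, p("hub_scores.tsv"), hash, seed)
    write_tsv(net$nodes, p("network_nodes.tsv"), hash, seed)
    write_tsv(drug_map$triples, p("drug_triples.tsv"), hash, seed)
    export_network(net, graphml_path = p("network.graphml"),
                   edges_path = p("network_edges.tsv"))
    message(sprintf(paste("[integrate] %d candidates, %d network nodes,",
                          "drug coverage %d/%d hubs"),
                    length(candidates), nrow(net$nodes),
                    drug_map$n_druggable, drug_map$n_genes))
    artifacts <- c(artifacts, candidates = p("candidates.txt"),
                   network_nodes = p("network_nodes.tsv"),
                   drug_triples = p("drug_triples.tsv"))
  }
  invisible(artifacts)
}

# Build all synthetic inputs for the demo pipeline from one config.
simulate_stage <- function(config) {
  seed <- config$seed
  roster <- config$mirnas
  active <- config$active_mirnas
  frac <- ifelse(roster %in% active, config$plate$active_fraction,
                 config$plate$inactive_fraction)
  design <- plate_design(roster, frac, n_cells = config$plate$n_cells,
                         control_fraction = config$plate$control_fraction)
  plate <- generate_plate(design, seed = child_seed(seed, 1L))
  truth <- plate_truth(plate)

  images <- list()
  n_render <- config$plate$render_wells %||% 0L
  if (n_render > 0L) {
    rdesign <- design[seq_len(min(n_render, nrow(design))), , drop = FALSE]
    rdesign$n_cells <- pmin(rdesign$n_cells, 30L)  # keep rendering light
    rplate <- generate_plate(rdesign, seed = child_seed(seed, 2L),
                             render = TRUE,
                             image_size = config$plate$image_size,
                             noise_sd = config$plate$noise_sd)
    images <- lapply(rplate$wells, `[[`, "image")
  }

  n_extra <- config$counts$n_mirnas - length(roster)
  ids <- c(roster, sprintf("mir_bg_%03d", seq_len(n_extra)))
  cfg <- count_sim_config(n_mirnas = config$counts$n_mirnas,
                          n_per_group = config$counts$n_per_group,
                          nb_dispersion = config$counts$nb_dispersion,
                          de_fraction = 0,
                          effect_log2fc = config$counts$effect_log2fc,
                          seed = child_seed(seed, 3L))
  counts <- simulate_counts(cfg, mirna_ids = ids)
  # plant the active roster miRNAs as up-regulated in the low-serum group
  up_idx <- match(active, ids)
  eff <- config$counts$effect_log2fc
  counts$truth$planted_log2fc[up_idx] <- eff
  low <- counts$groups == "low_serum"
  counts$counts[up_idx, low] <- with_seed(child_seed(seed, 4L), {
    mu <- pmax(rowMeans(counts$counts[up_idx, !low, drop = FALSE]), 1) *
      2^eff
    matrix(stats::rnbinom(length(up_idx) * sum(low),
                          mu = rep(mu, sum(low)),
                          size = 1 / config$counts$nb_dispersion),
           nrow = length(up_idx))
  })
  counts$lib_sizes <- colSums(counts$counts)

  genes <- sprintf("GENE%03d", seq_len(config$network$n_genes))
  shared_genes <- genes[1:5]
  clique_genes <- split(genes[6:23], rep(seq_along(active), length.out = 18L))
  plan <- fixture_plan(
    mirnas = active,
    gene_universe = genes,
    planted_shared = list("5" = shared_genes[1:2], "4" = shared_genes[3:5]),
    planted_hub_cliques = lapply(seq_along(active), function(i) {
      list(mirna = active[i], genes = clique_genes[[i]])
    }),
    drug_rows = data.frame(
      drug = sprintf("drug_%02d", seq_len(12L)),
      gene = rep(genes[6:17], length.out = 12L),
      stringsAsFactors = FALSE),
    n_filler_targets = config$network$n_filler_targets,
    ppi_extra_edges = config$network$ppi_extra_edges
  )
  fixtures <- generate_fixtures(plan, seed = child_seed(seed, 5L))
  list(design = design, plate_truth = truth, images = images,
       counts = counts, fixtures = fixtures)
}
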