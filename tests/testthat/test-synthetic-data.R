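test_that("render_well produces truth rows and is deterministic under a seed", {
  sp <- cell_specs(c(50, 150, 250), c(50, 150, 250),
                   c(20, 25, 15), c(20, 5, 10))
  w1 <- render_well(sp, image_size = 300, seed = 42)
  w2 <- render_well(sp, image_size = 300, seed = 42)
  w3 <- render_well(sp, image_size = 300, seed = 43)
  expect_identical(w1$image, w2$image)
  expect_false(identical(w1$image, w3$image))
  expect_equal(nrow(w1$truth), 3L)
  expect_equal(w1$truth$e_true, c(1, 5, 1.5))
  expect_true(all(w1$truth$e_true >= 1))
  expect_true(all(w1$truth$csi_true > 0 & w1$truth$csi_true <= 1))
  expect_true(all(w1$image >= 0 & w1$image <= 1))
})

test_that("render_well rejects overlapping and out-of-bounds cells", {
  overlapping <- cell_specs(c(50, 60), c(50, 60), c(20, 20), c(20, 20))
  expect_error(render_well(overlapping, image_size = 200), "overlap")
  out <- cell_specs(10, 10, 20, 20)
  expect_error(render_well(out, image_size = 200), "bounds")
  expect_error(cell_specs(50, 50, 5, 10))   # minor > major
})

test_that("generate_plate honors contractile_fraction limits and well counts", {
  des <- plate_design(c("c1", "c2"), c(0, 1), n_cells = 50)
  expect_equal(nrow(des), 9L)  # 3 replicates x (1 control + 2 treatments)
  plate <- generate_plate(des, seed = 1)
  expect_equal(length(plate$wells), 9L)
  truth <- plate_truth(plate)
  expect_true(all(truth$phenotype_true[truth$well_id == "A_c1"] == "synthetic"))
  expect_true(all(truth$phenotype_true[truth$well_id == "A_c2"] ==
                    "contractile"))
  expect_error(
    generate_plate(transform(des, contractile_fraction = 1.5)),
    "\\[0, 1\\]")
  no_ctrl <- des[!des$is_negative_control, ]
  expect_error(generate_plate(no_ctrl), "negative-control")
})

test_that("generated cell geometry keeps truth labels away from boundaries", {
  des <- plate_design("m", 0.5, n_cells = 300)
  truth <- plate_truth(generate_plate(des, seed = 8))
  con <- truth$phenotype_true == "contractile"
  expect_true(all(truth$e_true[con] > 3))
  expect_true(all(truth$csi_true[con] < 0.4))
  expect_true(all(truth$e_true[!con] > 1 & truth$e_true[!con] < 3))
  expect_true(all(truth$csi_true[!con] > 0.6))
})

test_that("simulate_counts plants the configured effects deterministically", {
  cfg0 <- count_sim_config(n_mirnas = 200, de_fraction = 0, seed = 5)
  sim0 <- simulate_counts(cfg0)
  expect_true(all(sim0$truth$planted_log2fc == 0))
  expect_identical(sim0$counts, simulate_counts(cfg0)$counts)

  cfg <- count_sim_config(n_mirnas = 1000, de_fraction = 0.1, seed = 5)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$planted_log2fc != 0), 100L)
  expect_true(all(abs(sim$truth$planted_log2fc[
    sim$truth$planted_log2fc != 0]) == cfg$effect_log2fc))
  expect_equal(sim$lib_sizes, colSums(sim$counts))
  expect_error(count_sim_config(nb_dispersion = 0), "positive")
  expect_error(count_sim_config(n_mirnas = 5, de_fraction = 0.1), ">= 1")
})

test_that("fixtures realize planted sharing, cliques and drug rows exactly", {
  plan <- fixture_plan(
    mirnas = paste0("m", 1:6),
    gene_universe = sprintf("G%03d", 1:300),
    planted_shared = list("5" = "gA", "4" = c("gB", "gC")),
    planted_hub_cliques = list(list(mirna = "m1", genes = paste0("q", 1:4))),
    drug_rows = data.frame(drug = character(), gene = character()),
    n_filler_targets = 10)
  fx <- generate_fixtures(plan, seed = 3)
  expect_equal(sum(fx$targets$gene == "gA"), 5L)
  expect_equal(length(unique(fx$targets$mirna[fx$targets$gene == "gA"])), 5L)
  # the planted 4-clique is pairwise connected
  pairs <- utils::combn(sort(paste0("q", 1:4)), 2)
  key <- paste(fx$ppi$gene_a, fx$ppi$gene_b)
  expect_true(all(paste(pairs[1, ], pairs[2, ]) %in% key))
  expect_equal(nrow(fx$drugs), 0L)
  # round trip: shared strata recovered exactly from the emitted table
  sh <- shared_targets(fx$targets)
  expect_identical(sh$gene[sh$k == 5], "gA")
  expect_setequal(sh$gene[sh$k == 4], c("gB", "gC"))
  # identical seed, identical output
  expect_identical(fx$targets, generate_fixtures(plan, seed = 3)$targets)
})

test_that("fixture plans with gene collisions are rejected", {
  expect_error(fixture_plan(paste0("m", 1:5), sprintf("G%03d", 1:300),
                            planted_shared = list("4" = "gA", "3" = "gA")),
               "collision")
  expect_error(fixture_plan(
    paste0("m", 1:5), sprintf("G%03d", 1:300),
    planted_shared = list("4" = "gA"),
    planted_hub_cliques = list(list(mirna = "m1", genes = c("gA", "gB")))),
    "collision")
})
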