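test_that("island clades are read off a Newick tree by stem and node ages", {
  ds <- extract_island_clades("((A:1,B:1):1,C:2);", c("A", "B"))
  expect_length(ds$clades, 1)
  expect_equal(ds$clades[[1]]$colonization_age, 2)
  expect_equal(ds$clades[[1]]$branching_ages, 1)
  expect_equal(ds$clades[[1]]$status, "endemic_clade")

  expect_error(extract_island_clades("((A:1,B:1):1,C:2);", c("A", "B", "C")),
               "non-island sister")
  expect_error(extract_island_clades("((A:1,B:2):1,C:3);", c("A", "B")),
               "ultrametric")
})

test_that("a dataset survives the tree round trip to 1e-9", {
  ds <- island_dataset(12, 40, list(
    end_clade(7, c(4, 2, 0.5), 1L, "a"),
    end_clade(3, 1.2, 2L, "b"),
    nes_clade(5, 3L, "c")
  ))
  tree <- dataset_to_tree(ds)
  back <- extract_island_clades(tree, island_tip_labels(ds), island_age = 12,
                                M = 40)
  expect_length(back$clades, 3)
  ages_in <- sort(vapply(ds$clades, `[[`, numeric(1), "colonization_age"))
  ages_out <- sort(vapply(back$clades, `[[`, numeric(1), "colonization_age"))
  expect_equal(ages_out, ages_in, tolerance = 1e-9)
  b_in <- sort(unlist(lapply(ds$clades, `[[`, "branching_ages")))
  b_out <- sort(unlist(lapply(back$clades, `[[`, "branching_ages")))
  expect_equal(b_out, b_in, tolerance = 1e-9)
})

test_that("simulated datasets survive the tree round trip", {
  p <- island_params(0.4, 0.1, Inf, 0.05, 0)
  set.seed(21)
  found <- 0
  while (found < 5) {
    sim <- simulate_iw(p, 8, 6)
    if (length(sim$clades) < 2 || anyDuplicated(
      vapply(sim$clades, `[[`, integer(1), "mainland_species_id"))) next
    found <- found + 1
    tree <- dataset_to_tree(sim)
    back <- extract_island_clades(tree, island_tip_labels(sim),
                                  island_age = sim$island_age, M = sim$M)
    expect_equal(sort(vapply(back$clades, `[[`, numeric(1), "colonization_age")),
                 sort(vapply(sim$clades, `[[`, numeric(1), "colonization_age")),
                 tolerance = 1e-9)
    expect_equal(sort(unlist(lapply(back$clades, `[[`, "branching_ages"))),
                 sort(unlist(lapply(sim$clades, `[[`, "branching_ages"))),
                 tolerance = 1e-9)
  }
})

test_that("missing-species insertion adds extant tips and stays ultrametric", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")

  zero <- insert_missing_species(tree, list(), n_replicates = 3)
  expect_length(zero, 3)
  for (t2 in zero) expect_identical(ape::write.tree(t2), ape::write.tree(tree))

  asg <- list(
    list(species = "X", mode = "tip_branch", anchor = "A"),
    list(species = "Y", mode = "within_clade", anchor = c("A", "B", "C"))
  )
  reps <- insert_missing_species(tree, asg, n_replicates = 10, seed = 4)
  for (t2 in reps) {
    expect_equal(ape::Ntip(t2), ape::Ntip(tree) + length(asg))
    ages <- islandDD:::node_ages(t2)
    expect_true(all(abs(ages[seq_len(ape::Ntip(t2))]) < 1e-9))
    expect_true(all(c("X", "Y") %in% t2$tip.label))
  }
  expect_error(insert_missing_species(tree, list(
    list(species = "Z", mode = "tip_branch", anchor = "nope"))), "not found")
})

test_that("tip-branch attachment heights are uniform along the anchor branch", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  set.seed(8)
  heights <- replicate(1000, {
    t2 <- insert_missing_species(tree, list(
      list(species = "X", mode = "tip_branch", anchor = "A")))[[1]]
    ages <- islandDD:::node_ages(t2)
    min(ages[ages > 1e-9]) # the new attachment node is the youngest split
  })
  # anchor branch spans ages (0, 1)
  expect_gt(stats::ks.test(heights, "punif", 0, 1)$p.value, 0.01)
})
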