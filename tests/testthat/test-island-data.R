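test_that("validation reports each broken invariant and passes clean data", {
  ok <- small_two_clade()
  expect_length(validate_dataset(ok), 0)

  bad <- island_dataset(30, 10, list(
    clade_record("x", 1, "endemic_clade", 22.09, c(25))), validate = FALSE)
  expect_match(validate_dataset(bad), "branching precedes colonization",
               all = FALSE)

  late <- island_dataset(30, 10, list(nes_clade(35)), validate = FALSE)
  expect_match(validate_dataset(late), "colonization predates island",
               all = FALSE)

  doublet <- island_dataset(30, 10, list(nes_clade(5, 3L, "a"),
                                         nes_clade(2, 3L, "b")),
                            validate = FALSE)
  expect_match(validate_dataset(doublet), "doublet", all = FALSE)

  singleton_branch <- island_dataset(30, 10, list(
    clade_record("s", 1, "non_endemic_singleton", 5, c(2))), validate = FALSE)
  expect_match(validate_dataset(singleton_branch), "singleton status",
               all = FALSE)

  # the five-clade fixture is valid for any seed
  expect_length(validate_dataset(make_table1_fixture(seed = 7)), 0)
})

test_that("event timeline merges clades, breaks ties deterministically and counts lineages", {
  empty <- island_dataset(30, 10, list())
  tl <- event_timeline(empty)
  expect_equal(tl$event, c("origin", "present"))
  expect_equal(tl$k_after, c(0L, 0L))

  ds <- make_table1_fixture(seed = 1)
  tl <- event_timeline(ds)
  col <- tl[tl$event == "colonization", ]
  expect_equal(col$age[1], 22.09)
  expect_equal(col$age[5], 8.43)
  expect_equal(tl$k_after[nrow(tl)], 65L)
  expect_true(all(diff(tl$age) <= 0))
  expect_true(all(tl$k_after - tl$k_before ==
                    as.integer(tl$event %in% c("colonization", "branching"))))

  # tie at the same age: colonization sorts before branching
  tie <- island_dataset(10, 5, list(end_clade(8, 5, 1L, "a"),
                                    nes_clade(5, 2L, "b")))
  tie$clades[[1]]$branching_ages <- 5
  tl2 <- event_timeline(tie)
  at5 <- tl2[tl2$age == 5, ]
  expect_equal(at5$event, c("colonization", "branching"))
})

test_that("JSON and TSV round trips preserve datasets to full precision", {
  ds <- make_table1_fixture(seed = 2)
  for (fmt in c("json", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_island_dataset(ds, path, fmt)
    back <- read_island_dataset(path, fmt)
    expect_equal(back$island_age, ds$island_age)
    expect_equal(back$M, ds$M)
    expect_length(back$clades, length(ds$clades))
    for (i in seq_along(ds$clades)) {
      expect_equal(back$clades[[i]]$colonization_age,
                   ds$clades[[i]]$colonization_age, tolerance = 1e-13)
      expect_equal(back$clades[[i]]$branching_ages,
                   ds$clades[[i]]$branching_ages, tolerance = 1e-13)
      expect_equal(back$clades[[i]]$status, ds$clades[[i]]$status)
      expect_equal(back$clades[[i]]$mainland_species_id,
                   ds$clades[[i]]$mainland_species_id)
    }
  }
})

test_that("write-read is the identity on a corpus of random datasets", {
  set.seed(99)
  path <- withr::local_tempfile(fileext = ".json")
  for (i in 1:1000) {
    ds <- random_dataset()
    write_island_dataset(ds, path, "json")
    back <- read_island_dataset(path, "json")
    expect_identical(total_species(back), total_species(ds))
    stopifnot(isTRUE(all.equal(ds[c("island_age", "M", "clades")],
                               back[c("island_age", "M", "clades")],
                               tolerance = 1e-13)))
  }
})

test_that("malformed files give informative parse errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"M": 5, "clades": []}', f)
  expect_error(read_island_dataset(f, "json"), "island_age")
  writeLines("not json at all {", f)
  expect_error(read_island_dataset(f, "json"), "parse")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# M=5", "clade_name\tmainland_species_id"), f2)
  expect_error(read_island_dataset(f2, "tsv"), "island_age")
})
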