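test_that("default region map matches the germarium geometry", {
  rm <- region_map()
  expect_equal(rm$n_cells_total, 18L)
  expect_equal(rm$n_cells_germline, 17L)
  expect_equal(rm$regions$GSC, 1L)
  expect_equal(rm$regions$CB, 2L)
  expect_equal(rm$regions$Cyst, 3:9)
  expect_equal(rm$regions$Posterior, 10:17)
  expect_error(region_map(gsc = 1:2, cb = 2), "contiguous")
})

test_that("condition labels are canonical and parse back", {
  expect_equal(condition_label(genetic_condition()), "WT")
  expect_equal(condition_label(genetic_condition(Nos = "null")), "Nos-/-")
  expect_equal(
    condition_label(genetic_condition(Brat = "doubled", Bam = "null")),
    "Bam-/- 2xBrat")
  for (lab in c("WT", "Nos-/-", "Dpp+/- Nos-/-", "2xBrat Bam-/-", "dMycOE")) {
    expect_equal(condition_label(parse_condition(lab)),
                 condition_label(parse_condition(
                   condition_label(parse_condition(lab)))))
  }
  expect_error(genetic_condition(Bam = "null", Bam = "doubled"),
               "conflicting")
  # the one allowed same-species combination: knockout + ectopic rescue
  expect_silent(genetic_condition(dMyc = "null", dMyc = "overexpress"))
})

test_that("packaged fixture has the published structure", {
  fx <- packaged_fixture()
  expect_equal(nrow(fx), 25L)
  expect_equal(sort(fx$index), 1:25)
  cats <- table(fx$category)
  expect_equal(unname(cats[["WildType"]]), 5L)
  expect_equal(unname(cats[["Behavioral"]]), 9L)
  expect_equal(unname(cats[["Mutant"]]), 11L)
  expect_equal(fx$index[fx$category == "WildType"], c(1:4, 12L))
  expect_equal(fx$index[fx$category == "Behavioral"], c(10L, 18:25))
  expect_equal(fx$index[fx$dynamic], 21:25)
  # behavioral category includes the Dpp heterozygote phenotype
  beh18 <- fx[fx$index == 18L, ]
  expect_equal(beh18$species, "Phenotype")
  expect_equal(beh18$condition, "Dpp+/-")
  # every species is an observable of the model family
  expect_true(all(fx$species %in%
                    c("pMad", "Bam", "Nos", "Brat", "Phenotype", "dMyc",
                      "Dpp")))
  # every condition parses
  expect_silent(lapply(fx$condition, parse_condition))
})

test_that("observation CSV round-trips field for field", {
  fx <- packaged_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(fx, path)
  back <- read_observations(path)
  expect_equal(as.data.frame(back), as.data.frame(fx))
})

test_that("reading rejects malformed observation tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste("index,species,condition,category,dynamic,n_categories,",
               "rank_GSC,rank_CB,rank_Cyst,rank_Posterior", sep = "")
  # header only: empty set
  writeLines(hdr, path)
  expect_equal(nrow(read_observations(path)), 0L)
  # rank outside 1..n_categories
  writeLines(c(hdr, "1,Nos,WT,WildType,FALSE,2,0,1,1,1"), path)
  expect_error(read_observations(path), "ranks must be")
  # unknown species
  writeLines(c(hdr, "1,Unobtainium,WT,WildType,FALSE,2,1,1,1,1"), path)
  expect_error(read_observations(path), "unknown species")
  # missing column
  writeLines(c("index,species", "1,Nos"), path)
  expect_error(read_observations(path), "missing column")
  # no observed region
  writeLines(c(hdr, "1,Nos,WT,WildType,FALSE,2,,,,"), path)
  expect_error(read_observations(path), "no observed region")
})

test_that("packaged fixture CSV matches the in-code encoding", {
  path <- system.file("extdata", "germarium_observations.csv",
                      package = "osfit")
  expect_true(nzchar(path))
  expect_equal(as.data.frame(read_observations(path)),
               as.data.frame(packaged_fixture()))
})
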