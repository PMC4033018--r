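test_that("packaged hominoid subcortical table loads with missing cells intact", {
  tab <- read_trait_table(
    allodev_example("tables/table1_hominoid_subcortical.csv"))
  expect_s3_class(tab, "individual_table")
  expect_equal(nrow(tab), 20L)
  expect_equal(length(unique(tab$species)), 8L)
  hs <- tab[tab$species == "Homo sapiens", ]
  expect_equal(sort(hs$striatum), c(9.551, 12.223))
  # the orangutan row printed with en dashes keeps its gaps as NA
  po5 <- tab[tab$specimen_id == "po5", ]
  expect_true(is.na(po5$amygdala))
  expect_equal(po5$hippocampus, 1.645)
  expect_equal(po5$striatum, 4.498)
  # hemisphere volumes are not published for these specimens
  expect_true(all(is.na(tab$hemisphere)))
})

test_that("specimen table validation rejects bad volumes and codes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,specimen_id,amygdala,hemisphere",
               "Pan troglodytes,a,-1,"), f)
  expect_error(read_trait_table(f), "non-positive.*row 1")

  writeLines(c("species,specimen_id,amygdala,hemisphere",
               "Pan troglodytes,a,0.5,"), f)
  expect_error(read_trait_table(f, laterality = c(amygdala = "both")),
               "unknown laterality")
  expect_error(read_trait_table(f, structures = "hippocampus"),
               "missing")

  # "-", "", "NA" and the en dash are all missing markers
  writeLines(c("species,specimen_id,amygdala,hippocampus,striatum,hemisphere",
               "Pan troglodytes,a,-,,NA,"), f)
  tab <- read_trait_table(f)
  expect_true(all(is.na(tab[1, c("amygdala", "hippocampus", "striatum")])))
})

test_that("duplicate specimens and empty tables are rejected", {
  df <- data.frame(species = c("A sp", "A sp"), specimen_id = c("1", "1"),
                   vol = c(1, 2), hemisphere = c(10, 10))
  expect_error(validate_individual_table(df, "vol"), "duplicate")
  expect_error(aggregate_species_means(
    validate_individual_table(df[0, ], "vol")), "empty")
})

test_that("species means average individuals with the halving rule applied once", {
  tab <- read_trait_table(
    allodev_example("tables/table1_hominoid_subcortical.csv"))
  sp <- aggregate_species_means(tab)
  expect_equal(nrow(sp), 8L)
  expect_equal(sp$striatum[sp$species == "Homo sapiens"],
               mean(c(9.551, 12.223)))
  expect_equal(sp$n_striatum[sp$species == "Homo sapiens"], 2L)
  # single contributing individual: mean is the value itself
  expect_equal(sp$amygdala[sp$species == "Hylobates lar"], 0.203)
  # species lacking a structure entirely keep NA there, with n = 0
  one <- data.frame(species = "X y", specimen_id = "1", a = 2.642,
                    b = NA_real_, hemisphere = NA_real_)
  agg <- aggregate_species_means(
    validate_individual_table(one, c("a", "b"),
                              laterality = c(a = "bilateral_sum")))
  expect_equal(agg$a, 1.321)      # bilateral sum halved once
  expect_true(is.na(agg$b))
  expect_equal(agg$n_b, 0L)
})

test_that("aggregation is invariant to row order and file splitting", {
  set.seed(4)
  df <- data.frame(
    species = rep(c("A a", "B b", "C c"), each = 4),
    specimen_id = as.character(1:12),
    vol = round(runif(12, 0.5, 3), 3),
    hemisphere = round(runif(12, 50, 90), 3))
  tab <- validate_individual_table(df, "vol")
  base <- aggregate_species_means(tab)
  shuf <- validate_individual_table(df[sample(12), ], "vol")
  resh <- aggregate_species_means(shuf)
  resh <- resh[match(base$species, resh$species), ]
  expect_equal(base$vol, resh$vol)
  expect_equal(base$hemisphere, resh$hemisphere)
  # splitting the table and pooling the parts' individuals changes nothing
  part <- rbind(df[1:5, ], df[6:12, ])
  expect_equal(aggregate_species_means(
    validate_individual_table(part, "vol"))$vol, base$vol)
})

test_that("pre-halved unilateral data equals raw bilateral data", {
  set.seed(9)
  df <- data.frame(species = rep(c("A a", "B b", "C c"), each = 3),
                   specimen_id = as.character(1:9),
                   vol = round(runif(9, 1, 4), 3),
                   hemisphere = NA_real_)
  raw <- aggregate_species_means(
    validate_individual_table(df, "vol", laterality = c(vol = "bilateral_sum")))
  pre <- df
  pre$vol <- pre$vol / 2
  halved <- aggregate_species_means(
    validate_individual_table(pre, "vol", laterality = c(vol = "unilateral")))
  expect_equal(raw$vol, halved$vol)
})

test_that("species-level tables round-trip through CSV exactly", {
  tab <- read_trait_table(
    allodev_example("tables/table1_hominoid_subcortical.csv"))
  sp <- aggregate_species_means(tab)
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp, f)
  back <- read_species_table(f)
  for (col in c("amygdala", "hippocampus", "striatum")) {
    expect_identical(back[[col]], sp[[col]])
  }
  expect_identical(back$species, sp$species)
})

test_that("Cavalieri estimator multiplies points, grid area and spacing", {
  expect_equal(cavalieri_volume(1000, 150, 1000), 1.5e-4)
  # volume is linear in section spacing
  expect_equal(cavalieri_volume(500, 150, 2000),
               2 * cavalieri_volume(500, 150, 1000))
  # longhand product for the hippocampus-scale parameter set
  p <- 29591; a <- 150; d <- 1290
  expect_equal(cavalieri_volume(p, a, d), p * a * d * 1e-12)
  expect_error(cavalieri_volume(0, 150, 1000), "positive")
  expect_error(cavalieri_volume(100, -1, 1000), "positive")
})
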