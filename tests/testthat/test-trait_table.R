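# Trait table reading, preprocessing and subgrouping.

write_toy_csv <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

toy_header <- "species,class,body_mass,sperm_length,clutch_size,testes_mass,genome_size"

test_that("well-formed tables read with all rows retained", {
  path <- write_toy_csv(c(toy_header,
                          "Rana_a,Amphibia,20,800,1000,0.1,5",
                          "Mus_b,Mammalia,25,120,8,0.2,3.3",
                          "Parus_c,Aves,18,95,9,0.15,1.2",
                          "Anolis_d,Reptilia,6,400,4,0.05,2.1"))
  tab <- read_trait_table(path)
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "n_dropped"), 0L)
})

test_that("rows lacking a required trait are dropped and counted", {
  path <- write_toy_csv(c(toy_header,
                          "A,Aves,10,100,,,",
                          "B,Aves,12,,,,",
                          "C,Aves,NA,90,,,",
                          "D,Aves,-3,90,,,"))
  expect_warning(
    expect_message(tab <- read_trait_table(path), "dropped"),
    "non-positive")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_dropped"), 3L)
  expect_equal(tab$species, "A")
})

test_that("duplicate species and missing required columns are rejected", {
  dup <- write_toy_csv(c(toy_header, "A,Aves,10,100,,,", "a,Aves,11,90,,,"))
  expect_error(read_trait_table(dup), "duplicate species")
  nocol <- write_toy_csv(c("species,class,body_mass", "A,Aves,10"))
  expect_error(read_trait_table(nocol), "missing required column")
})

test_that("non-numeric entries in numeric fields are flagged by row", {
  path <- write_toy_csv(c(toy_header, "A,Aves,10,100,many,,", "B,Aves,12,90,4,,"))
  expect_warning(tab <- read_trait_table(path), "row\\(s\\) 1")
  expect_true(is.na(tab$clutch_size[1]))
  expect_equal(tab$clutch_size[2], 4)
})

test_that("column mapping binds arbitrary headers", {
  path <- write_toy_csv(c("sp,grp,bm_g,sl_um", "A,Aves,100,10", "B,Aves,50,20"))
  tab <- read_trait_table(path, column_map = c(species = "sp", taxon_class = "grp",
                                               body_mass = "bm_g", sperm_length = "sl_um"))
  tab <- log10_traits(tab)
  expect_equal(tab$log10_body_mass, c(2, log10(50)))
  expect_equal(log10(50), 1.698970, tolerance = 1e-6)
  expect_equal(tab$log10_sperm_length[2], log10(20))
})

test_that("log10 transform handles exact powers and rejects non-positive values", {
  tab <- synthetic_trait_table(rbind(c(2, 0), c(1, 1)))
  tab2 <- log10_traits(tab)
  expect_equal(tab2$log10_body_mass, c(2, 1))
  expect_equal(tab2$log10_sperm_length, c(0, 1))
  tab$body_mass[1] <- -1
  expect_error(log10_traits(tab), "non-positive")
})

test_that("relative testes mass reproduces hand-computed OLS residuals", {
  # log10 pairs (0,0), (1,1), (2,0): slope 0, intercept 1/3
  tab <- data.frame(species = c("a", "b", "c"), taxon_class = "Aves",
                    body_mass = c(1, 10, 100), sperm_length = 1,
                    testes_mass = c(1, 10, 1), stringsAsFactors = FALSE)
  out <- relative_testes_mass(tab)
  expect_equal(out$rel_testes_mass, c(-1/3, 2/3, -1/3), tolerance = 1e-12)
})

test_that("residuals are zero for collinear data and sum to zero per class", {
  tab <- data.frame(species = letters[1:8],
                    taxon_class = rep(c("Aves", "Mammalia"), each = 4),
                    body_mass = rep(10^(1:4), 2), sperm_length = 1,
                    testes_mass = c(10^(1:4 * 0.7), 10^(1:4 * 1.2)),
                    stringsAsFactors = FALSE)
  out <- relative_testes_mass(tab)
  expect_equal(out$rel_testes_mass, rep(0, 8), tolerance = 1e-10)
  set.seed(7)
  tab$testes_mass <- tab$testes_mass * 10^rnorm(8, sd = 0.3)
  out <- relative_testes_mass(tab)
  for (cl in c("Aves", "Mammalia"))
    expect_equal(sum(out$rel_testes_mass[out$taxon_class == cl]), 0,
                 tolerance = 1e-10)
})

test_that("residuals are invariant to rescaling body mass within a class", {
  set.seed(11)
  tab <- data.frame(species = letters[1:6], taxon_class = "Mammalia",
                    body_mass = 10^runif(6, 1, 4), sperm_length = 1,
                    testes_mass = 10^runif(6, -1, 1), stringsAsFactors = FALSE)
  r1 <- relative_testes_mass(tab)$rel_testes_mass
  tab$body_mass <- tab$body_mass * 37
  r2 <- relative_testes_mass(tab)$rel_testes_mass
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("too few or degenerate testes records give missing residuals", {
  tab <- data.frame(species = c("a", "b", "c"), taxon_class = "Aves",
                    body_mass = c(10, 20, 30), sperm_length = 1,
                    testes_mass = c(1, 2, NA), stringsAsFactors = FALSE)
  expect_warning(out <- relative_testes_mass(tab), "fewer than 3")
  expect_true(all(is.na(out$rel_testes_mass)))
  tab$testes_mass <- c(1, 2, 3); tab$body_mass <- c(10, 10, 10)
  expect_warning(out <- relative_testes_mass(tab), "no body-mass variation")
  expect_true(all(is.na(out$rel_testes_mass)))
})

test_that("clutch z-scores centre and scale within class", {
  tab <- data.frame(species = letters[1:3], taxon_class = "Aves",
                    body_mass = 1, sperm_length = 1,
                    clutch_size = c(1, 2, 3), stringsAsFactors = FALSE)
  out <- clutch_zscore(tab)
  expect_equal(out$clutch_z, c(-1, 0, 1))
  expect_equal(mean(out$clutch_z), 0)
  expect_equal(sd(out$clutch_z), 1)
})

test_that("clutch z-scores preserve rank order under affine transforms", {
  set.seed(3)
  tab <- data.frame(species = letters[1:10], taxon_class = "Aves",
                    body_mass = 1, sperm_length = 1,
                    clutch_size = sample(1:50, 10), stringsAsFactors = FALSE)
  z1 <- clutch_zscore(tab)$clutch_z
  tab$clutch_size <- 3 * tab$clutch_size + 7
  z2 <- clutch_zscore(tab)$clutch_z
  expect_equal(z1, z2, tolerance = 1e-12)
  tab$clutch_size <- rep(5, 10)
  expect_warning(out <- clutch_zscore(tab), "zero clutch-size SD")
  expect_true(all(is.na(out$clutch_z)))
})

test_that("subgroup filters by class and by derived schemes", {
  tab <- data.frame(species = letters[1:4],
                    taxon_class = c("Aves", "Aves", "Amphibia", "Reptilia"),
                    body_mass = 1, sperm_length = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(subgroup(tab, "class", "Aves")), 2L)
  expect_equal(nrow(subgroup(tab, "thermoregulation", "endotherm")), 2L)
  expect_equal(nrow(subgroup(tab, "fertilization", "internal")), 3L)
  expect_equal(subgroup(tab, "fertilization", "external")$species, "c")
  expect_error(subgroup(tab, "class", "Insecta"), "valid levels")
  expect_error(subgroup(tab, "thermoregulation", "mesotherm"), "valid levels")
  # per-species override wins over the class mapping
  tab$fertilization <- c(NA, "external", NA, NA)
  expect_equal(subgroup(tab, "fertilization", "internal")$species, c("a", "d"))
})

test_that("written tables round-trip through the reader", {
  pts <- gen_triangle_cloud(30, seed = 5)
  tab <- preprocess_trait_table(synthetic_trait_table(pts))
  path <- tempfile(fileext = ".tsv")
  write_trait_table(tab, path)
  back <- read_trait_table(path)
  expect_equal(nrow(back), 30L)
  expect_equal(back$body_mass, tab$body_mass, tolerance = 1e-8)
})
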