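test_that("packaged profile table has the documented content", {
  tp <- taxon_profiles()
  expect_s3_class(tp, "taxon_profiles")
  expect_equal(nrow(tp), 24L)
  expect_equal(sum(tp$n_lakes), 238)

  pall <- tp[grepl("Pallasidae", tp$taxon), ]
  expect_equal(pall$mean_dha, 4.6)
  expect_equal(pall$class_dha, 5)

  iso <- tp[grepl("Isopoda", tp$taxon), ]
  expect_equal(iso$mean_ara, 4)
  expect_equal(iso$class_ara, 5)
  expect_equal(iso$mean_epa, 5)
  expect_equal(iso$class_epa, 2)

  # n = 1 taxa carry no SD and are never imputed at read time
  expect_true(is.na(tp$sd_ara[tp$taxon == "Nematoda"]))
})

test_that("profile tables round-trip through write_table", {
  tp <- taxon_profiles()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tp, path)
  back <- read_taxon_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tp))
})

test_that("profile reader rejects malformed and degenerate input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_taxon_table(path), "no records")

  tp <- taxon_profiles()
  bad <- tp
  bad$mean_ara[2] <- -1
  write_table(bad, path)
  expect_error(read_taxon_table(path), "finite and >= 0")

  hdr <- paste(readLines(system.file("extdata", "taxon_pufa_profiles.csv",
                                     package = "benthicpufa")), collapse = "\n")
  writeLines(c("taxon,n_lakes,mean_ara,sd_ara,class_ara,mean_epa,sd_epa,class_epa,mean_dha,sd_dha,class_dha",
               "A,3,oops,0.1,2,1,0.1,2,1,0.1,2",
               "B,3,1,0.1,2,1,0.1,2,1,0.1,2"), path)
  expect_error(read_taxon_table(path), "line 2")
})

test_that("class-1/not-detected coupling is enforced", {
  tp <- taxon_profiles()
  tp$class_dha[tp$taxon == "Ephemeroptera"] <- 2  # mean is 0
  expect_error(validate_taxon_profiles(tp), "not-detected")
})

test_that("surveys round-trip and validate covariates", {
  sv <- small_survey()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(sv, path)
  back <- read_survey(path)
  expect_equal(as.data.frame(back), as.data.frame(sv))
  expect_equal(attr(back, "taxa"), attr(sv, "taxa"))

  bad <- as.data.frame(sv)
  bad$ph[1] <- 0
  write_table(as.data.frame(bad), path)
  expect_error(read_survey(path), "strictly positive")
})

test_that("long-layout surveys are pivoted to the wide form", {
  sv <- small_survey()
  wide <- as.data.frame(sv)
  taxa <- attr(sv, "taxa")
  long <- reshape(wide, varying = taxa, v.names = "count",
                  times = taxa, timevar = "taxon", direction = "long")
  long$id <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(long, path)
  back <- read_survey(path, layout = "long")
  counts_back <- as.matrix(as.data.frame(back)[attr(back, "taxa")])
  counts_orig <- as.matrix(wide[taxa])[, colnames(counts_back)]
  expect_equal(unname(counts_back), unname(counts_orig))
})

test_that("survey invariants reject empty sites and duplicate site ids", {
  counts <- matrix(c(1, 0, 0, 0), 2, 2,
                   dimnames = list(NULL, c("A", "B")))
  expect_error(make_survey(counts), "abundance > 0")
  counts2 <- matrix(1, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(make_survey(counts2, lake_id = c("L1", "L1"),
                           site_id = c("s1", "s1")), "unique")
})

test_that("write_table handles empty and generic records", {
  tp <- taxon_profiles()[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tp, path)
  expect_length(readLines(path), 1L)  # header only

  resp <- data.frame(lake_id = c("a", "b", "c"), site_id = "s1",
                     richness = 1:3)
  write_table(resp, path)
  expect_length(readLines(path), 4L)
})

test_that("lake metadata validates surface area", {
  meta <- data.frame(lake_id = "L1", name = "Synthetic lake", area = 120,
                     color = 40, tn = 400, tp = 12)
  expect_s3_class(as_lake_meta(meta), "lake_meta")
  meta$area <- 0
  expect_error(as_lake_meta(meta), "area")
})
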