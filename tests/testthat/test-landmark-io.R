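test_that("CSV round trip preserves coordinates to full precision", {
  ds <- random_dataset(n = 3, k = 6, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(ds, f)
  back <- read_landmark_table(f)
  expect_identical(back$labels, ds$labels)
  expect_equal(back$coords, ds$coords, tolerance = 0)
  expect_identical(back$info$specimen_id, ds$info$specimen_id)
})

test_that("CSV reader validates structure and reports offenders", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f)
  expect_error(read_landmark_table(f), "format error")

  # missing column
  writeLines("specimen_id,genotype,age,trial,landmark,x,y", f)
  expect_error(read_landmark_table(f), "missing column.*z")

  # non-numeric coordinate names the row
  writeLines(c("specimen_id,genotype,age,trial,landmark,x,y,z",
               "s1,affected,E15.5,1,a,1,2,3",
               "s1,affected,E15.5,1,b,1,oops,3"), f)
  expect_error(read_landmark_table(f), "parse error.*oops")

  # inconsistent label sets list the offending configuration
  writeLines(c("specimen_id,genotype,age,trial,landmark,x,y,z",
               "s1,affected,E15.5,1,a,0,0,0",
               "s1,affected,E15.5,1,b,1,0,0",
               "s2,affected,E15.5,1,a,0,0,0",
               "s2,affected,E15.5,1,c,1,0,0"), f)
  expect_error(read_landmark_table(f), "inconsistent.*s2")
})

test_that("a full chondrocranial table reads with K = 25", {
  labs <- chondro_landmarks()
  expect_length(labs, 25)
  set.seed(4)
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(specimen_id = "s1", genotype = "affected",
                    age = "E15.5", trial = 1, landmark = labs,
                    x = runif(25), y = runif(25), z = runif(25))
  write.csv(tab, f, row.names = FALSE)
  ds <- read_landmark_table(f)
  expect_length(ds$labels, 25)
  expect_equal(n_configurations(ds), 1)
})

test_that("TPS LM3 blocks are read, SCALE records ignored", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=3",
               "0.0 0.0 0.0", "1.0 0.0 0.0", "0.0 2.0 0.0",
               "ID=spec_a", "SCALE=0.001",
               "LM3=3",
               "0.5 0.0 0.0", "1.5 0.0 0.0", "0.5 2.0 0.0",
               "ID=spec_b"), f)
  ds <- read_landmark_table(f, dialect = "tps")
  expect_equal(n_configurations(ds), 2)
  expect_identical(ds$info$specimen_id, c("spec_a", "spec_b"))
  expect_equal(ds$coords[2, 1, ], c(x = 0.5, y = 0, z = 0))
})

test_that("replicate averaging: identical trials give zero error", {
  one <- random_dataset(n = 1, k = 5, seed = 2)
  coords <- array(NA_real_, dim = c(2, 5, 3))
  coords[1, , ] <- one$coords[1, , ]
  coords[2, , ] <- one$coords[1, , ]
  two <- landmark_dataset(coords, one$labels, specimen_id = "s01",
                          genotype = "unaffected", age = "E15.5",
                          trial = 1:2)
  out <- average_replicates(two)
  expect_equal(out$dataset$coords[1, , ], one$coords[1, , ],
               ignore_attr = TRUE)
  expect_true(all(out$errors$error_pct == 0))
  expect_false(any(out$errors$flagged))
})

test_that("replicate error exactly at threshold is not flagged", {
  base <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2), 4, 3,
                 byrow = TRUE)
  labels <- letters[1:4]
  # displace landmark 1 of trial 2 along x by exactly 5% of the mean
  # inter-landmark distance of the trial-averaged configuration
  delta0 <- 1
  for (iter in 1:50) {  # fixed-point: displacement feeds into the mean
    avg <- base
    avg[1, 1] <- avg[1, 1] + delta0 / 2
    delta0 <- 0.05 * mean(dist(avg))
  }
  trial2 <- base
  trial2[1, 1] <- trial2[1, 1] + delta0
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- base
  coords[2, , ] <- trial2
  ds <- landmark_dataset(coords, labels, specimen_id = "s1",
                         trial = 1:2)
  out <- average_replicates(ds, max_error_pct = 5)
  e1 <- out$errors$error_pct[out$errors$landmark == "a"]
  expect_equal(e1, 5, tolerance = 1e-9)
  # flag rule: only errors strictly greater than the threshold flag, so
  # an error exactly at the threshold passes
  out_eq <- average_replicates(ds, max_error_pct = e1)
  expect_false(out_eq$errors$flagged[out_eq$errors$landmark == "a"])
  out2 <- average_replicates(ds, max_error_pct = e1 - 1e-6)
  expect_true(out2$errors$flagged[out2$errors$landmark == "a"])
})

test_that("replicate errors match an independent recomputation", {
  set.seed(9)
  k <- 6
  base <- matrix(runif(k * 3, 0, 5), k, 3)
  coords <- array(NA_real_, dim = c(2, k, 3))
  coords[1, , ] <- base + rnorm(k * 3, sd = 0.05)
  coords[2, , ] <- base + rnorm(k * 3, sd = 0.05)
  ds <- landmark_dataset(coords, letters[1:k], specimen_id = "s1",
                         trial = 1:2)
  out <- average_replicates(ds)
  # oracle: direct per-landmark recomputation
  avg <- (coords[1, , ] + coords[2, , ]) / 2
  md <- mean(dist(avg))
  oracle <- 100 * sqrt(rowSums((coords[1, , ] - coords[2, , ])^2)) / md
  expect_equal(out$errors$error_pct, unname(oracle), tolerance = 1e-12)
  expect_equal(out$dataset$coords[1, , ], avg, ignore_attr = TRUE)
})

test_that("averaging commutes with translation", {
  set.seed(10)
  coords <- array(rnorm(2 * 5 * 3, sd = 2), dim = c(2, 5, 3))
  ds <- landmark_dataset(coords, letters[1:5], specimen_id = "s1",
                         trial = 1:2)
  shifted <- transform_dataset(ds, diag(3), shift = c(3, -1, 7))
  a1 <- transform_dataset(average_replicates(ds)$dataset, diag(3),
                          shift = c(3, -1, 7))
  a2 <- average_replicates(shifted)$dataset
  expect_equal(a1$coords, a2$coords, tolerance = 1e-12)
})

test_that("single-trial specimens error unless allowed", {
  ds <- random_dataset(n = 1, k = 4, seed = 3)
  expect_error(average_replicates(ds), "at least 2")
  out <- average_replicates(ds, min_trials = 1)
  expect_equal(out$dataset$coords, ds$coords, tolerance = 0)
})

test_that("region selection subsets, reorders, and validates", {
  labs <- chondro_landmarks()
  set.seed(5)
  coords <- array(runif(2 * 25 * 3, 0, 8), dim = c(2, 25, 3))
  ds <- landmark_dataset(coords, labs, specimen_id = c("s1", "s2"),
                         genotype = "affected", age = "E15.5")
  mi <- select_region(ds, "chondro_MI")
  expect_identical(mi$labels, c("laottr", "lncse", "lttr", "psep",
                                "raottr", "rncse", "rttr"))
  expect_identical(mi$info$genotype, c("affected", "affected"))
  # idempotence and nested composition
  expect_equal(select_region(mi, "chondro_MI"), mi)
  # composing two nested selections equals the inner selection
  lw <- select_region(ds, "chondro_lateral_wall")
  inner <- region_spec("roof", c("laottr", "lttr", "rttr"))
  expect_equal(select_region(lw, inner), select_region(ds, inner))
  # identity on the full label set
  full <- select_region(ds, region_spec("all", labs))
  expect_equal(full$coords, ds$coords, tolerance = 0)
  # unknown label is named
  expect_error(select_region(mi, region_spec("bad", c("lttr", "nope"))),
               "nope")
})

test_that("built-in region definitions have the published sizes", {
  rg <- cranio_regions()
  expect_identical(sort(rg$chondro_MI$labels),
                   sort(c("laottr", "lncse", "lttr", "psep", "raottr",
                          "rncse", "rttr")))
  expect_identical(sort(rg$dermato_MI$labels),
                   sort(c("laif", "lalf", "lpfl", "lpto", "raif",
                          "rpfl", "rpto")))
  expect_length(rg$chondro_MI$labels, 7)
  expect_length(rg$dermato_MI$labels, 7)
  expect_length(rg$global_skull$labels, 24)
  expect_length(rg$chondro_olfactory$labels, 10)
  expect_length(rg$chondro_braincase_floor$labels, 7)
  expect_length(rg$chondro_lateral_wall$labels, 8)
  # every chondro region label exists in the full chondro landmark set
  for (r in c("chondro_olfactory", "chondro_braincase_floor",
              "chondro_lateral_wall", "chondro_MI")) {
    expect_true(all(rg[[r]]$labels %in% chondro_landmarks()), info = r)
  }
})
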