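# Model YAML dialect and motion-table round trips.

test_that("bundled walker inventory matches its construction", {
  expect_equal(nrow(walker$segments), 7)
  expect_equal(sum(walker$joints$type == "revolute"), 6)
  expect_equal(sum(walker$joints$type == "planar-free-base"), 1)
  expect_equal(length(walker$muscles), 18)
  expect_equal(nrow(walker$contact_spheres), 6)
  expect_equal(sum(walker$contact_spheres$segment == "foot_r"), 3)
  expect_equal(sum(walker$contact_spheres$heel), 2)
  expect_equal(sum(walker$segments$mass), 65.4, tolerance = 1e-9)
  expect_setequal(unique(muscle_groups(walker)),
                  c("vastus", "biceps_femoris", "semitendinosus",
                    "tibialis_anterior", "soleus", "gastrocnemius", "other"))
})

test_that("model YAML round-trips to an equivalent definition", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model(walker, f)
  m2 <- read_model(f)
  expect_equal(m2$segments, walker$segments, tolerance = 1e-12)
  expect_equal(m2$contact_spheres, walker$contact_spheres, tolerance = 1e-12)
  expect_equal(names(m2$muscles), names(walker$muscles))
  for (nm in names(walker$muscles)) {
    expect_equal(unclass(m2$muscles[[nm]]$params),
                 unclass(walker$muscles[[nm]]$params), tolerance = 1e-12)
    expect_equal(m2$muscles[[nm]]$path, walker$muscles[[nm]]$path,
                 tolerance = 1e-12)
  }
  # a second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_model(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("model validation names the offending entry", {
  bad <- walker
  bad$muscles[[3]]$path$segment[2] <- "femur_L"
  expect_error(validate_model(bad), "femur_L")
  bad2 <- walker
  bad2$segments$mass[2] <- -1
  expect_error(validate_model(bad2), "non-positive mass.*thigh_r")
  bad3 <- walker
  bad3$joints$parent[2] <- "shank_r"  # thigh_r <-> shank_r cycle
  expect_error(validate_model(bad3), "cycle|connected")
  bad4 <- walker
  bad4$muscles[[1]]$path <- bad4$muscles[[1]]$path[1, , drop = FALSE]
  expect_error(validate_model(bad4), "at least 2 path points")
  expect_error(read_model(tempfile()), "not found")
})

test_that(".mot degrees round-trip recovers radians to 1e-9", {
  mot <- reference_motion_table(walker_ref)
  f <- withr::local_tempfile(fileext = ".mot")
  write_motion(mot, f, in_degrees = TRUE)
  back <- read_motion(f)
  expect_equal(names(back), names(mot))
  for (j in setdiff(names(mot), "time"))
    expect_equal(back[[j]], mot[[j]], tolerance = 1e-9)
  # header declares the degree flag
  expect_true(any(grepl("inDegrees=yes", readLines(f))))
})

test_that("CSV dialect round-trips and flags defective tables", {
  act <- synthetic_activation_traces(walker)
  f <- withr::local_tempfile(fileext = ".csv")
  write_motion(act, f)
  back <- read_motion(f, "csv", activation = TRUE)
  expect_equal(as.matrix(back), as.matrix(act), tolerance = 1e-12)

  shuffled <- act
  shuffled$time <- sample(shuffled$time)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuffled, f2, row.names = FALSE)
  expect_error(read_motion(f2, "csv"), "non-monotonic|non-uniform")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f3)
  expect_error(read_motion(f3, "csv"))

  f4 <- withr::local_tempfile(fileext = ".mot")
  writeLines(character(0), f4)
  expect_error(read_motion(f4), "empty")

  f5 <- withr::local_tempfile(fileext = ".mot")
  writeLines(c("junk", "endheader", "time\ta", "0\t1", "0.01\t2\t3"), f5)
  expect_error(read_motion(f5), "ragged row at line 5")
})

test_that("run manifests record command, seed and version", {
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(f, "synth-gait", list(speed = 1.34), seed = 11)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$command, "synth-gait")
  expect_equal(doc$seed, 11)
  expect_equal(doc$package, "planargait")
})

test_that("the bundled walker file loads to the full inventory", {
  f <- system.file("extdata", "planar_walker.yaml", package = "planargait")
  m <- read_model(f)
  expect_equal(nrow(m$segments), 7)
  expect_equal(sum(m$joints$type == "revolute"), 6)
  expect_equal(length(m$muscles), 18)
  expect_equal(nrow(m$contact_spheres), 6)
  # equivalent to the in-code builder
  expect_equal(m$segments, walker$segments, tolerance = 1e-9)
  g1 <- planargait:::cpp_muscle_geometry(planargait:::model_core(m),
                                         default_q(m))
  g2 <- planargait:::cpp_muscle_geometry(planargait:::model_core(walker),
                                         default_q(walker))
  expect_equal(g1$L, g2$L, tolerance = 1e-9)
})
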