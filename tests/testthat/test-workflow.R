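small_paced_config <- function(id = "paced", seed = 1L) {
  geom <- build_sheet_geometry(41, 41, 0.05)
  prot <- stimulus_protocol(list(list(label = "S1", onset = 5, duration = 2,
                                      amplitude = 40, center = c(1, 1, 0),
                                      radius = 0.12)))
  list(id = id, geom = geom, params = tissue_params(duration = 60),
       protocol = prot, cell_model = "nygren", seed = seed)
}

small_focal_config <- function(id = "focal", seed = 1L) {
  geom <- build_sheet_geometry(41, 41, 0.05)
  prot <- protocol_focal(list(
    list(center = c(0.6, 1, 0), radius = 0.15, onsets = c(10, 460),
         label = "F+"),
    list(center = c(1.4, 1, 0), radius = 0.15, onsets = c(10, 460),
         label = "F-")))
  list(id = id, geom = geom,
       params = tissue_params(sigma = 1.0, duration = 700),
       protocol = prot, cell_model = "alievpanfilov", seed = seed)
}

test_that("build_library persists entries with protocol-derived ground truth", {
  dir <- withr::local_tempdir()
  idx <- build_library(list(small_paced_config(), small_focal_config()), dir)
  expect_equal(idx$valid, c(TRUE, TRUE))
  expect_equal(idx$n_events, c(1L, 4L))  # 1 P + (2 sources x 2 beats)

  ent <- load_library_entry(dir, "paced")
  expect_s3_class(ent$record, "vm_record")
  expect_equal(ent$truth$type, "P")
  expect_equal(ent$truth$ref_time, 5)
  expect_length(ent$acts, nrow(ent$record$geometry$nodes))

  ent2 <- load_library_entry(dir, "focal")
  expect_setequal(unique(ent2$truth$type), c("F+", "F-"))
  expect_equal(nrow(ent2$truth), 4)

  # an empty config list is a valid (empty) library
  dir2 <- withr::local_tempdir()
  expect_equal(nrow(build_library(list(), dir2)), 0)
})

test_that("a failing entry is marked invalid without harming the others", {
  dir <- withr::local_tempdir()
  bad <- small_paced_config("bad")
  bad$cell_model <- "no-such-model"
  expect_warning(idx <- build_library(list(bad, small_paced_config("ok")),
                                      dir),
                 "failed")
  expect_equal(idx$valid, c(FALSE, TRUE))
  expect_s3_class(load_library_entry(dir, "ok")$record, "vm_record")
})

test_that("rebuilding with the same seed reproduces identical activation tables", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_library(list(small_paced_config(seed = 7L)), d1)
  build_library(list(small_paced_config(seed = 7L)), d2)
  expect_identical(readLines(file.path(d1, "paced", "acts.csv")),
                   readLines(file.path(d2, "paced", "acts.csv")))
  expect_identical(readLines(file.path(d1, "paced", "truth.json")),
                   readLines(file.path(d2, "paced", "truth.json")))
})

test_that("surface-point export is blinded and round-trips", {
  dir <- withr::local_tempdir()
  build_library(list(small_paced_config()), dir)
  ent <- load_library_entry(dir, "paced")
  f <- file.path(dir, "surface.csv")
  export_surface_points(ent, f)
  df <- read.csv(f)
  expect_identical(names(df), c("id", "x", "y", "z"))  # schema: no Vm/AcT
  expect_equal(nrow(df), length(ent$record$geometry$surface_nodes))
  expect_equal(as.matrix(df[, c("x", "y", "z")]),
               ent$record$geometry$nodes[ent$record$geometry$surface_nodes, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the blinded session enforces protocol order and reproducibility", {
  dir <- withr::local_tempdir()
  build_library(list(small_paced_config()), dir)
  ent <- load_library_entry(dir, "paced")
  ses <- new_session(ent, master_seed = 11L)
  expect_error(issue_blinded_electrograms(ses), "protocol order")

  ua <- place_uniform_array(ent$record$geometry, c(1, 1, 0), rows = 4,
                            cols = 4, pitch = 0.3)
  ses <- register_electrodes(ses, ua)
  expect_error(declare_noise(ses, rep(0.5, 3)), "one noise level")
  ses <- declare_noise(ses, 0.5)
  f <- file.path(dir, "egms.csv")
  ses <- issue_blinded_electrograms(ses, path = f)
  # export schema: time plus one column per electrode, nothing else
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_identical(hdr, c("time_ms", ua$labels))
  # re-issue with the stored seed is identical
  ses2 <- issue_blinded_electrograms(ses)
  expect_identical(ses$issued$egms$phi_e, ses2$issued$egms$phi_e)
  # noise declarations are honored per electrode
  clean <- compute_electrograms(ent$record, ua)
  pert <- ses$issued$egms$phi_e - clean$phi_e
  expect_lte(max(abs(pert)), 0.5)
  expect_gt(max(abs(pert)), 0)
})

test_that("feeding the silver standard back as predictions scores perfectly", {
  dir <- withr::local_tempdir()
  build_library(list(small_paced_config()), dir)
  ent <- load_library_entry(dir, "paced")
  ses <- new_session(ent, master_seed = 2L)
  ua <- place_uniform_array(ent$record$geometry, c(1, 1, 0), rows = 4,
                            cols = 4, pitch = 0.3)
  ses <- register_electrodes(ses, ua)
  ses <- declare_noise(ses, 0)
  ses <- issue_blinded_electrograms(ses)

  sites <- unique(ua$nearest_node)
  act_pred <- do.call(rbind, lapply(sites, function(s)
    if (length(ent$acts[[as.character(s)]]) > 0)
      data.frame(site_id = s, act_ms = ent$acts[[as.character(s)]])))
  truth_site <- mapeval:::nearest_surface_node(
    ent$record$geometry, as.matrix(ent$truth[, c("x", "y", "z")]))
  pat_pred <- data.frame(type = ent$truth$type, beat = ent$truth$beat,
                         site_id = truth_site,
                         time_ms = ent$truth$ref_time)
  ses <- ingest_predictions(ses, act_pred, pat_pred)
  rep <- evaluate_session(ses, tol = 2)
  expect_equal(rep$act$actpm, 100)
  expect_equal(rep$act$rms, 0)
  expect_true(all(rep$patterns$per_type$acppm == 100))

  # empty predictions: nothing correct
  ses0 <- ingest_predictions(ses, data.frame(site_id = integer(0),
                                             act_ms = numeric(0)), NULL)
  rep0 <- evaluate_session(ses0)
  expect_equal(rep0$act$fC, 0)
  expect_equal(rep0$act$actpm, 0)
})

test_that("predictions at unknown sites are rejected and reports match the schema", {
  dir <- withr::local_tempdir()
  build_library(list(small_paced_config()), dir)
  ent <- load_library_entry(dir, "paced")
  ses <- new_session(ent, 3L)
  ua <- place_uniform_array(ent$record$geometry, c(1, 1, 0), rows = 4,
                            cols = 4, pitch = 0.3)
  ses <- register_electrodes(ses, ua)
  ses <- declare_noise(ses, 0)
  ses <- issue_blinded_electrograms(ses)
  expect_error(ingest_predictions(ses, data.frame(site_id = 99999,
                                                  act_ms = 10)),
               "not in the issued surface-point set")

  s <- unique(ua$nearest_node)[1]
  ses <- ingest_predictions(ses, data.frame(site_id = s, act_ms = 20))
  f <- file.path(dir, "report.json")
  evaluate_session(ses, path = f)
  rep_json <- jsonlite::read_json(f)
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "mapeval"))
  expect_true(all(unlist(schema$required) %in% names(rep_json)))
  for (fld in unlist(schema$properties$act$required)) {
    expect_true(fld %in% names(rep_json$act))
  }
  # blinded exports never carry ground-truth fields
  expect_false(any(c("vm", "act_ms", "type") %in% names(rep_json$sweep[[1]])))
})
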