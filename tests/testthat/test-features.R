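mk_bp_store <- function(sys = 120, dia = 80, pseudonym = "P-1", date = "2024-01-01") {
  store <- omop_store("t")
  rows <- rbind(
    hdsnode:::omop_row(pseudonym, source_value = "systolic_bp",
                       value_as_number = sys, event_date = date, group_id = "bp-1"),
    hdsnode:::omop_row(pseudonym, source_value = "diastolic_bp",
                       value_as_number = dia, event_date = date, group_id = "bp-1"))
  rows$row_id <- 1:2
  store$tables$Measurement <- rows
  store
}

test_that("features are quarantined at registration and gated until audited", {
  fs <- feature_store()
  def <- pulse_pressure_feature()
  register_feature(fs, def)
  expect_equal(fs$features[["pulse_pressure@1"]]$state, "quarantined")
  store <- mk_bp_store()
  expect_error(compute_feature(fs, "pulse_pressure", 1L, store),
               class = "hds_conflict_error")
  expect_error(register_feature(fs, def), class = "hds_conflict_error")
  audit_feature(fs, "pulse_pressure", 1L, auditor = "admin")
  expect_equal(fs$features[["pulse_pressure@1"]]$state, "deployed")
  audits <- vapply(fs$audit, `[[`, "", "event")
  expect_true("audited" %in% audits)
  # versions must strictly increase
  expect_error(register_feature(fs, pulse_pressure_feature()),
               class = "hds_conflict_error")
  expect_error(feature_definition("x", "person", function(s) NULL,
                                  "Measurement", author = "", description = "d"),
               class = "hds_validation_error")
})

test_that("pulse pressure computes systolic minus diastolic per reading", {
  fs <- feature_store()
  register_feature(fs, pulse_pressure_feature())
  audit_feature(fs, "pulse_pressure", 1L, auditor = "admin")
  vs <- compute_feature(fs, "pulse_pressure", 1L, mk_bp_store(120, 80))
  expect_false(vs$failed)
  expect_equal(unname(unlist(vs$values)), 40)
  expect_named(vs$values, "P-1|2024-01-01")
})

test_that("value sets are keyed by level and survive as compact JSON", {
  fs <- feature_store()
  person_count <- feature_definition(
    "measurement_count", "person", input_tables = "Measurement",
    author = "a", description = "rows per person",
    generator = function(store) {
      tab <- table(store$tables$Measurement$person_pseudonym)
      setNames(as.numeric(tab), names(tab))
    })
  register_feature(fs, person_count)
  audit_feature(fs, "measurement_count", 1L, auditor = "admin")
  th <- generate_telehealth_export(50, 2, seed = 11)
  store <- omop_store("t")
  ingest(store, th, telehealth_measurements_converter(),
         function(pid) paste0("P-", pid), vocabulary_map())
  vs <- compute_feature(fs, "measurement_count", 1L, store)
  expect_length(vs$values, 50)
  js <- feature_values_json(fs, "measurement_count", 1L)
  expect_equal(jsonlite::fromJSON(js)$values[["P-TP001"]], 8)  # 2 days x 4 rows
})

test_that("a failing generator is recorded without poisoning the store", {
  fs <- feature_store()
  boom <- feature_definition("boom", "person", input_tables = "Measurement",
                             author = "a", description = "fails",
                             generator = function(store) stop("kaput"))
  register_feature(fs, boom)
  audit_feature(fs, "boom", 1L, auditor = "admin")
  store <- mk_bp_store()
  vs <- compute_feature(fs, "boom", 1L, store)
  expect_true(vs$failed)
  expect_match(vs$diagnostics, "kaput")
  expect_equal(nrow(store$tables$Measurement), 2)  # store untouched
})

test_that("only features whose inputs intersect the batch are recomputed", {
  fs <- feature_store()
  register_feature(fs, pulse_pressure_feature())
  audit_feature(fs, "pulse_pressure", 1L, auditor = "admin")
  obs_feat <- feature_definition("wellbeing_days", "observation",
                                 input_tables = "Observation",
                                 author = "a", description = "d",
                                 generator = function(store) {
                                   o <- store$tables$Observation
                                   o <- o[o$source_value == "wellbeing", ]
                                   setNames(rep(1, nrow(o)),
                                            paste(o$person_pseudonym, o$event_date, sep = "|"))
                                 })
  register_feature(fs, obs_feat)
  audit_feature(fs, "wellbeing_days", 1L, auditor = "admin")

  store <- omop_store("t")
  attach_feature_store(fs, store)
  th <- generate_telehealth_export(3, 3, seed = 12)
  r1 <- ingest(store, th, telehealth_measurements_converter(),
               function(pid) paste0("P-", pid), vocabulary_map())
  # Measurement batch: pulse pressure computed, observation feature not
  expect_false(is.null(fs$values[["pulse_pressure@1"]]))
  expect_null(fs$values[["wellbeing_days@1"]])
  report <- on_data_update(fs, store, r1$batch)
  expect_equal(report$recomputed[report$feature == "pulse_pressure@1"], TRUE)
  expect_equal(report$recomputed[report$feature == "wellbeing_days@1"], FALSE)
  # empty batch -> empty report
  expect_equal(nrow(on_data_update(fs, store, list(counts = integer(0)))), 0)

  pp_before <- fs$values[["pulse_pressure@1"]]
  r2 <- ingest(store, th, telehealth_observations_converter(),
               function(pid) paste0("P-", pid), vocabulary_map())
  expect_false(is.null(fs$values[["wellbeing_days@1"]]))
  expect_identical(fs$values[["pulse_pressure@1"]]$values, pp_before$values)
})

test_that("stored values equal a from-scratch recomputation and the matrix is complete", {
  fs <- feature_store()
  register_feature(fs, pulse_pressure_feature())
  audit_feature(fs, "pulse_pressure", 1L, auditor = "admin")
  map_feat <- feature_definition("map_mean", "measurement", input_tables = "Measurement",
                                 author = "a", description = "mean arterial pressure",
                                 generator = function(store) {
                                   m <- store$tables$Measurement
                                   s <- m[m$source_value == "systolic_bp", ]
                                   d <- m[m$source_value == "diastolic_bp", ]
                                   j <- merge(s[, c("person_pseudonym", "event_date", "group_id",
                                                    "value_as_number")],
                                              d[, c("group_id", "value_as_number")],
                                              by = "group_id", suffixes = c("_s", "_d"))
                                   setNames((j$value_as_number_s + 2 * j$value_as_number_d) / 3,
                                            paste(j$person_pseudonym, j$event_date, sep = "|"))
                                 })
  register_feature(fs, map_feat)
  audit_feature(fs, "map_mean", 1L, auditor = "admin")

  store <- omop_store("t")
  attach_feature_store(fs, store)
  resolver <- function(pid) paste0("P-", pid)
  for (seed in 13:14) {
    th <- generate_telehealth_export(4, 3, seed = seed)
    ingest(store, th, telehealth_measurements_converter(), resolver, vocabulary_map())
  }
  stored <- fs$values[["pulse_pressure@1"]]$values
  fresh <- compute_feature(fs, "pulse_pressure", 1L, store)$values
  expect_identical(stored[order(names(stored))], fresh[order(names(fresh))])

  mat <- build_feature_matrix(fs, "measurement")
  keys <- unique(c(names(stored), names(fs$values[["map_mean@1"]]$values)))
  expect_equal(nrow(mat), length(keys))
  expect_equal(ncol(mat), 3)  # key + 2 deployed features
  expect_false(anyNA(mat$pulse_pressure))
  expect_warning(m0 <- build_feature_matrix(feature_store(), "person"))
  expect_equal(nrow(m0), 0)
})

test_that("a person lacking a value gets the missing marker", {
  fs <- feature_store()
  f1 <- feature_definition("f1", "person", input_tables = "Person",
                           author = "a", description = "d",
                           generator = function(store) c(A = 1, B = 2))
  f2 <- feature_definition("f2", "person", input_tables = "Person",
                           author = "a", description = "d",
                           generator = function(store) c(A = 10))
  for (f in list(f1, f2)) register_feature(fs, f)
  audit_feature(fs, "f1", 1L, auditor = "x"); audit_feature(fs, "f2", 1L, auditor = "x")
  store <- omop_store("t")
  compute_feature(fs, "f1", 1L, store); compute_feature(fs, "f2", 1L, store)
  mat <- build_feature_matrix(fs, "person")
  expect_equal(mat$key, c("A", "B"))
  expect_equal(mat$f1, c(1, 2))
  expect_equal(mat$f2, c(10, NA))
})

test_that("the model store round-trips bytes and gates predictions on audit", {
  ms <- model_store()
  blob <- serialize(list(w = rnorm(5)), NULL, version = 2L)
  store_model(ms, "m1", 1L, blob)
  expect_identical(retrieve_model(ms, "m1", 1L), blob)
  expect_error(store_model(ms, "m1", 1L, blob), class = "hds_conflict_error")
  expect_error(predict_model(ms, "m1", 1L, 1), class = "hds_conflict_error")

  store_model(ms, "const", 1L, function(x) 0.42)
  expect_error(predict_model(ms, "const", 1L, 5), class = "hds_conflict_error")
  audit_model(ms, "const", 1L, auditor = "admin")
  expect_equal(predict_model(ms, "const", 1L, 5), 0.42)
  expect_error(retrieve_model(ms, "nope"), class = "hds_not_found_error")
})
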