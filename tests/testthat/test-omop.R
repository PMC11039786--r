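vmap_test <- vocabulary_map(system.file("extdata", "vocab_demo.csv", package = "hdsnode"))

test_that("vocabulary mapping is deterministic with ingredient fallback", {
  hit <- map_concept("local_obs", "systolic_bp", vmap_test)
  expect_equal(hit$concept_id, "8480-6")
  expect_equal(hit$vocabulary, "LOINC")
  expect_false(hit$unmapped)

  fb <- map_concept("drug_brand", "Lasix", vmap_test)
  expect_equal(fb$concept_id, "C03CA01")
  expect_equal(fb$vocabulary, "ATC")
  expect_equal(fb$mapping_note, "ingredient-fallback")

  unk <- map_concept("drug_brand", "Nonexistol", vmap_test)
  expect_true(unk$unmapped)
  expect_equal(unk$concept_name, "Nonexistol")  # source value retained
})

test_that("telehealth ingest writes the declared row expansion with provenance", {
  th <- generate_telehealth_export(10, 10, seed = 4)   # 100 patient-days
  store <- omop_store("tele")
  resolver <- function(pid) paste0("P-", pid)
  r <- ingest(store, th, telehealth_measurements_converter(), resolver, vmap_test)
  m <- store$tables$Measurement
  # 2 Measurement rows per blood-pressure reading, as separate components
  expect_equal(sum(m$source_value == "systolic_bp"), 100)
  expect_equal(sum(m$source_value == "diastolic_bp"), 100)
  expect_equal(r$rows_written, 400)  # + heart rate + bodyweight
  # systolic/diastolic of one reading share the group id
  sys <- m[m$source_value == "systolic_bp", ]
  dia <- m[m$source_value == "diastolic_bp", ]
  expect_setequal(sys$group_id, dia$group_id)
  # provenance on every row
  expect_true(all(m$converter_id == "telehealth-measurements"))
  expect_true(all(m$converter_version == "1"))
  expect_true(all(nzchar(m$batch_id)))
  expect_length(store$batches, 1)
  expect_equal(store$batches[[1]]$counts[["Measurement"]], 400)
})

test_that("an empty payload writes zero rows but one batch log entry", {
  store <- omop_store("tele")
  empty <- generate_telehealth_export(1, 1, seed = 1)
  empty$notes <- empty$notes[0, ]
  r <- ingest(store, empty, telehealth_notes_converter(), function(p) "P", vmap_test)
  expect_equal(r$rows_written, 0)
  expect_length(store$batches, 1)
})

test_that("re-ingesting an identical batch is fingerprint-detected and skipped", {
  th <- generate_telehealth_export(3, 3, seed = 5)
  store <- omop_store("tele")
  resolver <- function(pid) paste0("P-", pid)
  r1 <- ingest(store, th, telehealth_measurements_converter(), resolver, vmap_test)
  r2 <- ingest(store, th, telehealth_measurements_converter(), resolver, vmap_test)
  expect_true(r2$batch$skipped)
  expect_equal(r2$rows_written, 0)
  expect_equal(nrow(store$tables$Measurement), r1$rows_written)
  expect_length(store$batches, 2)  # the skip is logged too
})

test_that("FHIR QuestionnaireResponse conversion follows the 1 + 1 + n rule", {
  qr <- generate_questionnaire_response(27, seed = 6)
  rows <- fhir_questionnaire_etl(qr, function(s) "P-EDC")
  expect_equal(nrow(rows$VisitOccurrence), 1)
  expect_equal(nrow(rows$SurveyConduct), 1)
  expect_equal(nrow(rows$Observation), 27)
  expect_equal(rows$SurveyConduct$value_as_string, "completed")
  expect_true(all(rows$Observation$person_pseudonym == "P-EDC"))

  qr0 <- generate_questionnaire_response(0, seed = 6)
  rows0 <- fhir_questionnaire_etl(qr0, function(s) "P-EDC")
  expect_null(rows0$Observation)
  expect_equal(nrow(rows0$VisitOccurrence) + nrow(rows0$SurveyConduct), 2)

  qr_bad <- qr; qr_bad$subject <- NULL
  expect_error(fhir_questionnaire_etl(qr_bad, identity), class = "hds_validation_error")
  expect_error(fhir_questionnaire_etl("{\"resourceType\": \"Patient\"}", identity),
               class = "hds_parse_error")
})

test_that("exports round-trip and CSV/JSON agree on record counts", {
  th <- generate_telehealth_export(4, 4, seed = 7)
  store <- omop_store("tele")
  resolver <- function(pid) paste0("P-", pid)
  ingest(store, th, telehealth_measurements_converter(), resolver, vmap_test)
  ingest(store, th, telehealth_observations_converter(), resolver, vmap_test)
  dir <- withr::local_tempdir()
  pc <- export_tables(store, c("Measurement", "Observation"), "csv", file.path(dir, "csv"))
  pj <- export_tables(store, c("Measurement", "Observation"), "json", file.path(dir, "json"))
  store2 <- omop_store("copy")
  import_tables(store2, pc)
  expect_equal(nrow(store2$tables$Measurement), nrow(store$tables$Measurement))
  expect_equal(store2$tables$Measurement$value_as_number,
               store$tables$Measurement$value_as_number)
  js <- jsonlite::fromJSON(pj[["Measurement"]])
  expect_equal(nrow(js), nrow(store$tables$Measurement))
  expect_error(export_tables(store, "Nope", "csv", dir), class = "hds_not_found_error")
})

test_that("no identity trait reaches the data store or its exports", {
  ids <- generate_identities(15, 0, seed = 9)
  idx <- person_index()
  ps <- vapply(ids$records, function(r) {
    register_identity(idx, r, "tele", "secret")$pseudonym
  }, character(1))
  th <- generate_telehealth_export(15, 3, seed = 9,
                                   patient_ids = sprintf("T%03d", 1:15))
  store <- omop_store("tele")
  resolver <- function(pid) ps[match(pid, sprintf("T%03d", 1:15))]
  ingest(store, th, telehealth_measurements_converter(), resolver, vmap_test)
  ingest(store, th, telehealth_notes_converter(), resolver, vmap_test)
  traits <- unique(c(vapply(ids$records, function(r) r$traits$first_name, ""),
                     vapply(ids$records, function(r) r$traits$last_name, ""),
                     vapply(ids$records, function(r) r$traits$date_of_birth, "")))
  expect_length(scan_for_traits(store, traits), 0)
  dir <- withr::local_tempdir()
  paths <- export_tables(store, "Measurement", "csv", dir)
  blob <- paste(readLines(paths[[1]], warn = FALSE), collapse = "\n")
  expect_false(any(vapply(traits, grepl, logical(1), x = blob, fixed = TRUE)))
})

test_that("annotation corpora are de-identified, counted and label-guarded", {
  store <- omop_store("tele")
  texts <- c("Herr Gruber klagt über Atemnot.",
             "Rückruf unter +43 664 8123456 erbeten.",
             "Therapie unverändert.")
  rows <- do.call(rbind, lapply(seq_along(texts), function(i) {
    df <- hdsnode:::omop_row("P-1", source_value = "clinical_note",
                             value_as_string = texts[i], event_date = "2024-01-01")
    df
  }))
  rows$row_id <- seq_len(nrow(rows))
  store$tables$Note <- rows
  corp <- build_annotation_corpus(store, corpus_id = "c1")
  expect_equal(nrow(corp), 3)
  rules <- default_ruleset()
  for (tx in corp$text) expect_equal(nrow(detect_entities(tx, rules)), 0)
  attach_label(store, "c1", corp$note_id[1], "dyspnea")
  expect_error(attach_label(store, "c1", 999, "x"), class = "hds_not_found_error")
  store$tables$Note <- store$tables$Note[0, ]
  expect_warning(build_annotation_corpus(store, corpus_id = "c2"))
})

test_that("converters cannot write undeclared tables and queries are audited", {
  rogue <- etl_converter("rogue", 1L, "x", target_tables = "Note",
                         transform = function(p, rp, v) {
                           list(rows = list(Measurement = hdsnode:::omop_row("P", source_value = "s")))
                         })
  store <- omop_store("t")
  expect_error(ingest(store, list(), rogue, identity, vmap_test),
               class = "hds_validation_error")
  expect_error(etl_converter("bad", 1L, "x", function(...) NULL, target_tables = "Death"),
               class = "hds_config_error")
  query_table(store, "Measurement", "SELECT * FROM Measurement WHERE 1=1")
  expect_length(store$query_log, 1)
  expect_error(query_table(store, "Nope"), class = "hds_not_found_error")
})
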