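#' Typo model for planted duplicates
#'
#' Per planted duplicate exactly one edit is drawn from the configured
#' operation weights: single-character substitution, deletion, insertion,
#' adjacent transposition (all applied to a name trait), or a day/month
#' swap in the date of birth (falls back to a substitution when the day
#' cannot be a month).
#'
#' @param substitution,deletion,insertion,transposition,date_swap
#'   non-negative weights; at least one must be positive.
#' @return object of class `typo_model`.
#' @export
typo_model <- function(substitution = 1, deletion = 1, insertion = 1,
                       transposition = 1, date_swap = 1) {
  w <- c(substitution = substitution, deletion = deletion, insertion = insertion,
         transposition = transposition, date_swap = date_swap)
  if (any(w < 0) || !any(w > 0)) config_error("typo model needs at least one positive edit weight")
  structure(list(weights = w / sum(w)), class = "typo_model")
}

apply_typo <- function(traits, model) {
  op <- sample(names(model$weights), 1L, prob = model$weights)
  if (op == "date_swap") {
    dob <- traits$date_of_birth
    day <- as.integer(substr(dob, 9, 10))
    if (day >= 1 && day <= 12) {
      traits$date_of_birth <- paste0(substr(dob, 1, 4), "-", substr(dob, 9, 10),
                                     "-", substr(dob, 6, 7))
      return(traits)
    }
    op <- "substitution"  # day cannot be a month; degrade to a name edit
  }
  field <- sample(c("first_name", "last_name"), 1L)
  s <- traits[[field]]
  n <- nchar(s)
  letters_pool <- letters
  traits[[field]] <- switch(op,
    substitution = {
      i <- sample.int(n, 1L)
      repl <- sample(setdiff(letters_pool, tolower(substr(s, i, i))), 1L)
      paste0(substr(s, 1, i - 1L), repl, substr(s, i + 1L, n))
    },
    deletion = if (n > 1L) {
      i <- sample.int(n, 1L)
      paste0(substr(s, 1, i - 1L), substr(s, i + 1L, n))
    } else s,
    insertion = {
      i <- sample.int(n + 1L, 1L) - 1L
      paste0(substr(s, 1, i), sample(letters_pool, 1L), substr(s, i + 1L, n))
    },
    transposition = if (n > 1L) {
      i <- sample.int(n - 1L, 1L)
      paste0(substr(s, 1, i - 1L), substr(s, i + 1L, i + 1L),
             substr(s, i, i), substr(s, i + 2L, n))
    } else s
  )
  traits
}

#' Generate synthetic identities with planted duplicates
#'
#' Draws `n` base patient identities from the packaged name pools and
#' appends `round(n * duplicate_rate)` duplicate records, each derived from
#' a distinct base record by one edit from the [typo_model()]. The pairing
#' of duplicates with their base records is recorded as ground truth.
#'
#' @param n number of base records (>= 1).
#' @param duplicate_rate fraction in `[0, 1)` of planted duplicates.
#' @param typo_model a [typo_model()].
#' @param seed integer seed; equal seeds give byte-identical output.
#' @param ssn_coverage fraction of base records carrying a social security
#'   number (the trait is optional in the field).
#' @param source_context node identifier stamped on the records.
#' @return object of class `synthetic_identity_set` with `records` (list of
#'   [identity_record()]), `truth_links` (two-column matrix of record index
#'   pairs denoting the same person) and `seed`.
#' @export
generate_identities <- function(n, duplicate_rate = 0, typo_model = hdsnode::typo_model(),
                                seed = 1L, ssn_coverage = 0.7,
                                source_context = "synthetic") {
  if (!is_count(n)) config_error("n must be a positive integer")
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate >= 1) {
    config_error("duplicate_rate must lie in [0, 1)")
  }
  if (!inherits(typo_model, "typo_model")) config_error("typo_model must be a typo_model object")
  with_seed(seed, {
    first <- sample(.hds_first_names, n, replace = TRUE)
    last <- sample(.hds_last_names, n, replace = TRUE)
    dob <- format(as.Date("1930-01-01") + sample.int(25000L, n, replace = TRUE), "%Y-%m-%d")
    has_ssn <- runif(n) < ssn_coverage
    ssn <- ifelse(has_ssn,
                  sprintf("%04d%s", sample.int(9999L, n, replace = TRUE),
                          format(as.Date(dob), "%d%m%y")),
                  NA_character_)
    records <- lapply(seq_len(n), function(i) {
      tr <- list(first_name = first[i], last_name = last[i], date_of_birth = dob[i])
      if (has_ssn[i]) tr$ssn <- ssn[i]
      identity_record(tr, entity_kind = "patient", source_context = source_context)
    })
    n_dup <- round(n * duplicate_rate)
    links <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("a", "b")))
    if (n_dup > 0L) {
      base_idx <- sample.int(n, n_dup)   # distinct bases: links are trivially closed
      for (j in seq_len(n_dup)) {
        bi <- base_idx[j]
        tr <- records[[bi]]$traits
        tr <- apply_typo(tr, typo_model)
        records[[length(records) + 1L]] <-
          identity_record(tr, entity_kind = "patient", source_context = source_context)
        links <- rbind(links, c(bi, length(records)))
      }
    }
    structure(
      list(records = records, truth_links = links, seed = as.integer(seed)),
      class = "synthetic_identity_set"
    )
  })
}

#' @export
print.synthetic_identity_set <- function(x, ...) {
  cat(sprintf("<synthetic_identity_set> %d records, %d planted duplicate pairs (seed %d)\n",
              length(x$records), nrow(x$truth_links), x$seed))
  invisible(x)
}

#' Write identities to CSV
#'
#' @param set a `synthetic_identity_set`.
#' @param path output CSV path (columns record_id, first_name, last_name,
#'   date_of_birth, ssn).
#' @export
write_identities_csv <- function(set, path) {
  stopifnot(inherits(set, "synthetic_identity_set"))
  df <- identities_as_data_frame(set)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

identities_as_data_frame <- function(set) {
  data.frame(
    record_id = seq_along(set$records),
    first_name = vapply(set$records, function(r) r$traits$first_name, character(1)),
    last_name = vapply(set$records, function(r) r$traits$last_name, character(1)),
    date_of_birth = vapply(set$records, function(r) r$traits$date_of_birth, character(1)),
    ssn = vapply(set$records, function(r) r$traits$ssn %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

# ---- notes with planted PII -------------------------------------------------

.note_fillers <- c(
  "Blutdruck heute stabil, keine Beschwerden.",
  "Gewicht im Zielbereich, Therapie unverändert fortführen.",
  "Patient berichtet leichte Atemnot bei Belastung.",
  "Medikament wurde gut vertragen, keine Nebenwirkungen.",
  "Kontrolle in zwei Wochen vereinbart.",
  "Selbstmessung regelmäßig durchgeführt, Werte plausibel.",
  "Befinden heute gut, Puls ruhig und regelmäßig."
)

plant_entity <- function(type, dicts, counters) {
  pick <- function(pool, key) {
    i <- counters[[key]] %||% 0L
    counters[[key]] <- i + 1L
    pool[(i %% length(pool)) + 1L]
  }
  switch(type,
    patient = {
      nm <- pick(dicts$internal_names, "internal")
      list(prefix = "Herr ", surface = nm, suffix = " meldet sich telefonisch.")
    },
    person = {
      nm <- pick(dicts$public_names, "public")
      list(prefix = "Begleitperson ", surface = nm, suffix = " war anwesend.")
    },
    healthcare_professional = {
      nm <- pick(dicts$professional_names, "prof")
      list(prefix = "Befund durch Dr. ", surface = nm, suffix = " erstellt.")
    },
    location = {
      loc <- pick(dicts$locations, "loc")
      list(prefix = "Patient wohnt in ", surface = loc, suffix = ".")
    },
    address = {
      st <- pick(dicts$streets, "street")
      no <- pick(as.character(2:49), "streetno")
      list(prefix = "Hausbesuch in der ", surface = paste0(st, " ", no), suffix = " geplant.")
    },
    zip_code = {
      zip <- pick(c("6020", "6060", "6130", "6330", "6500", "9900"), "zip")
      list(prefix = "Postleitzahl ", surface = zip, suffix = " im Einzugsgebiet.")
    },
    phone_number = {
      ph <- pick(c("+43 664 8123456", "+43 512 504123", "0664 8123457", "0512 504124"), "phone")
      list(prefix = "Rückruf unter ", surface = ph, suffix = " erbeten.")
    },
    email_address = {
      em <- pick(c("anna.gruber@example.at", "j.huber@klinik-beispiel.at",
                   "pflege.team@telemed-beispiel.at"), "email")
      list(prefix = "Antwort an ", surface = em, suffix = " senden.")
    },
    website = {
      ws <- pick(c("www.telemed-beispiel.at", "https://portal.beispiel-klinik.at/login"), "web")
      list(prefix = "Anleitung unter ", surface = ws, suffix = " verfügbar.")
    }
  )
}

.deid_entity_types <- c("patient", "person", "healthcare_professional", "location",
                        "address", "zip_code", "phone_number", "email_address", "website")

#' Generate clinical notes with planted PII and gold annotations
#'
#' Each note embeds at least one planted entity; entity types are assigned
#' round-robin over the nine recognized types so every type occurs once at
#' least every nine plants. Planted names are drawn from the supplied
#' dictionaries and every surface form is recorded as a gold span (0-based,
#' half-open character offsets).
#'
#' @param n number of notes (>= 1).
#' @param dictionaries name lists as from [default_dictionaries()].
#' @param seed integer seed.
#' @param strata optional character vector of stratum labels cycled over
#'   the notes (generic; no semantics attached).
#' @return list of `synthetic_note` objects with fields `note_id`, `text`,
#'   `gold_spans` (data frame start/end/entity_type/surface),
#'   `patient_pseudonym`, `author` and `stratum`.
#' @export
generate_notes_with_pii <- function(n, dictionaries = default_dictionaries(),
                                    seed = 1L, strata = NULL) {
  if (!is_count(n)) config_error("n must be a positive integer")
  needed <- c("internal_names", "public_names", "professional_names", "locations", "streets")
  for (d in needed) {
    if (!length(dictionaries[[d]])) config_error(paste0("dictionary '", d, "' is empty"))
  }
  counters <- new.env(parent = emptyenv())
  type_i <- 0L
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      n_ent <- 1L + (i %% 3L)
      text <- ""
      spans <- data.frame(start = integer(0), end = integer(0),
                          entity_type = character(0), surface = character(0),
                          stringsAsFactors = FALSE)
      for (j in seq_len(n_ent)) {
        type_i <<- type_i + 1L
        type <- .deid_entity_types[((type_i - 1L) %% 9L) + 1L]
        ent <- plant_entity(type, dictionaries, counters)
        if (nzchar(text)) text <- paste0(text, " ")
        start <- nchar(text) + nchar(ent$prefix)
        text <- paste0(text, ent$prefix, ent$surface, ent$suffix)
        spans <- rbind(spans, data.frame(start = start, end = start + nchar(ent$surface),
                                         entity_type = type, surface = ent$surface,
                                         stringsAsFactors = FALSE))
      }
      text <- paste0(text, " ", sample(.note_fillers, 1L))
      structure(
        list(note_id = sprintf("note-%04d", i), text = text, gold_spans = spans,
             patient_pseudonym = sprintf("SYNPAT%06d", sample.int(999999L, 1L)),
             author = sprintf("author-%02d", (i %% 7L) + 1L),
             stratum = if (!is.null(strata)) strata[((i - 1L) %% length(strata)) + 1L] else NA_character_),
        class = "synthetic_note"
      )
    })
  })
}

#' Write notes (with gold spans) as JSON lines
#'
#' @param notes list of `synthetic_note` objects.
#' @param path output path; one JSON object per line.
#' @export
write_notes_jsonl <- function(notes, path) {
  lines <- vapply(notes, function(nt) {
    as.character(jsonlite::toJSON(
      list(note_id = nt$note_id, text = nt$text,
           patient_pseudonym = nt$patient_pseudonym, author = nt$author,
           gold_spans = nt$gold_spans),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

# ---- telehealth export ------------------------------------------------------

#' Physiologic bounds for the telehealth generator
#'
#' @param systolic,diastolic,heart_rate,bodyweight two-element numeric
#'   ranges (mmHg, mmHg, bpm, kg).
#' @return named list of ranges.
#' @export
telehealth_bounds <- function(systolic = c(95, 180), diastolic = c(55, 110),
                              heart_rate = c(45, 130), bodyweight = c(48, 140)) {
  list(systolic = systolic, diastolic = diastolic,
       heart_rate = heart_rate, bodyweight = bodyweight)
}

#' Generate a synthetic telehealth export
#'
#' Emulates a home-telemonitoring source system: per patient and day one
#' blood-pressure reading (systolic/diastolic, mmHg), one heart-rate
#' reading (bpm), one bodyweight (kg), one self-reported wellbeing score
#' (good/medium/bad), one medication record (prescription plus
#' self-reported intake adherence) and, on a fraction of days, a free-text
#' clinical note. Values follow a stable per-patient baseline plus daily
#' noise, clamped to the physiologic bounds.
#'
#' @param patients number of patients (>= 1).
#' @param days number of days (>= 1).
#' @param seed integer seed.
#' @param patient_ids optional explicit patient identifiers (length
#'   `patients`); defaults to `TP001`, `TP002`, ...
#' @param start_date first day of the series.
#' @param bounds physiologic bounds, see [telehealth_bounds()].
#' @return object of class `telehealth_export`: data frames
#'   `blood_pressure`, `heart_rate`, `bodyweight`, `wellbeing`,
#'   `medication`, `notes`.
#' @export
generate_telehealth_export <- function(patients, days, seed = 1L,
                                       patient_ids = NULL,
                                       start_date = as.Date("2024-01-01"),
                                       bounds = telehealth_bounds()) {
  if (!is_count(patients) || !is_count(days)) {
    config_error("patients and days must be positive integers")
  }
  if (is.null(patient_ids)) patient_ids <- sprintf("TP%03d", seq_len(patients))
  stopifnot(length(patient_ids) == patients)
  dates <- format(start_date + seq_len(days) - 1L, "%Y-%m-%d")
  clamp <- function(x, r) pmin(pmax(round(x, 1), r[1]), r[2])
  with_seed(seed, {
    grid <- expand.grid(patient_id = patient_ids, date = dates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$patient_id, grid$date), , drop = FALSE]
    rownames(grid) <- NULL
    base_sys <- setNames(runif(patients, 110, 150), patient_ids)
    base_dia <- setNames(base_sys - runif(patients, 35, 55), patient_ids)
    base_hr <- setNames(runif(patients, 55, 90), patient_ids)
    base_wt <- setNames(runif(patients, 55, 110), patient_ids)
    m <- nrow(grid)
    bp <- cbind(grid, reading_id = paste0("bp-", grid$patient_id, "-", grid$date),
                systolic = clamp(base_sys[grid$patient_id] + rnorm(m, 0, 8), bounds$systolic),
                diastolic = clamp(base_dia[grid$patient_id] + rnorm(m, 0, 6), bounds$diastolic))
    hr <- cbind(grid, heart_rate = clamp(base_hr[grid$patient_id] + rnorm(m, 0, 6), bounds$heart_rate))
    wt <- cbind(grid, bodyweight = clamp(base_wt[grid$patient_id] + rnorm(m, 0, 0.6), bounds$bodyweight))
    wb <- cbind(grid, wellbeing = sample(c("good", "medium", "bad"), m,
                                         replace = TRUE, prob = c(0.6, 0.3, 0.1)))
    drug_i <- sample.int(nrow(.hds_drugs), patients, replace = TRUE)
    med <- cbind(grid,
                 drug_brand = .hds_drugs$brand[drug_i[match(grid$patient_id, patient_ids)]],
                 prescribed = TRUE,
                 intake_adherent = runif(m) > 0.08)
    has_note <- runif(m) < 0.15
    notes <- cbind(grid[has_note, , drop = FALSE],
                   note_text = sample(.note_fillers, sum(has_note), replace = TRUE))
    rownames(notes) <- NULL
    structure(
      list(blood_pressure = bp, heart_rate = hr, bodyweight = wt,
           wellbeing = wb, medication = med, notes = notes,
           bounds = bounds, seed = as.integer(seed)),
      class = "telehealth_export"
    )
  })
}

#' @export
print.telehealth_export <- function(x, ...) {
  cat(sprintf("<telehealth_export> %d blood-pressure readings, %d notes (seed %d)\n",
              nrow(x$blood_pressure), nrow(x$notes), x$seed))
  invisible(x)
}

#' Write a telehealth export as one CSV per table
#'
#' @param export a `telehealth_export`.
#' @param dir output directory (created if absent).
#' @export
write_telehealth_csv <- function(export, dir) {
  stopifnot(inherits(export, "telehealth_export"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("blood_pressure", "heart_rate", "bodyweight", "wellbeing",
                "medication", "notes")) {
    write.csv(export[[tab]], file.path(dir, paste0(tab, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Generate a synthetic FHIR QuestionnaireResponse
#'
#' A completed quality-of-life form in FHIR R4 shape: `n_items` answered
#' items (7-point coded answers), a subject reference and a completion
#' status. Item texts are generic quality-of-life stems.
#'
#' @param n_items number of answered items (0 allowed).
#' @param subject FHIR subject reference string.
#' @param seed integer seed.
#' @param questionnaire canonical questionnaire reference.
#' @param status completion status.
#' @return a list in FHIR QuestionnaireResponse shape (serialize with
#'   `jsonlite::toJSON(x, auto_unbox = TRUE)`).
#' @export
generate_questionnaire_response <- function(n_items = 27L, subject = "Patient/example-1",
                                            seed = 1L,
                                            questionnaire = "Questionnaire/qol-27",
                                            status = "completed") {
  if (!is.numeric(n_items) || n_items < 0 || n_items != floor(n_items)) {
    config_error("n_items must be a non-negative integer")
  }
  with_seed(seed, {
    items <- lapply(seq_len(n_items), function(i) {
      list(linkId = sprintf("item-%02d", i),
           text = sprintf("Quality-of-life item %d (last 2 weeks)", i),
           answer = list(list(valueCoding = list(
             system = "urn:example:qol-scale",
             code = as.character(sample.int(7L, 1L))))))
    })
    list(resourceType = "QuestionnaireResponse",
         id = sprintf("qr-%06d", sample.int(999999L, 1L)),
         questionnaire = questionnaire,
         status = status,
         subject = list(reference = subject),
         authored = "2024-03-15T10:00:00+01:00",
         item = items)
  })
}
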