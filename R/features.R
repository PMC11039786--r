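#' Define a feature generator
#'
#' A feature is versioned source code plus metadata. The generator is an R
#' function `function(store)` returning a named vector/list of values:
#' keys are the person pseudonym at person level and
#' `pseudonym|date` (the event key) at observation and measurement level.
#' The source code is captured with the definition so peers can audit and
#' re-run it.
#'
#' @param name feature name.
#' @param level `"person"`, `"observation"` or `"measurement"`.
#' @param generator the generator function.
#' @param input_tables OMOP tables the generator reads (drives
#'   recomputation on data updates).
#' @param author,description metadata (required).
#' @param version integer version.
#' @param technology implementation technology label.
#' @return object of class `feature_definition` (state `quarantined`).
#' @export
feature_definition <- function(name, level = c("person", "observation", "measurement"),
                               generator, input_tables, author, description,
                               version = 1L, technology = "R") {
  level <- match.arg(level)
  if (missing(author) || !nzchar(author)) validation_error("feature metadata requires an author")
  if (missing(description) || !nzchar(description)) {
    validation_error("feature metadata requires a description")
  }
  stopifnot(is.function(generator))
  bad <- setdiff(input_tables, .omop_tables)
  if (length(bad)) config_error(paste0("unknown input table: ", bad[[1]]))
  structure(
    list(name = name, level = level, generator = generator,
         input_tables = input_tables, version = as.integer(version),
         state = "quarantined",
         metadata = list(author = author, timestamp = now_stamp(),
                         source_code = paste(deparse(generator), collapse = "\n"),
                         technology = technology, description = description)),
    class = "feature_definition"
  )
}

#' Create a feature store
#'
#' Registry of audited feature-generation code and its computed values at
#' person, observation or measurement granularity. Freshly registered
#' features are quarantined and only executable after an administrator
#' audit deploys them; values are stored per feature as compact JSON-able
#' keyed structures and aggregated on demand into a per-level feature
#' matrix.
#'
#' @return an environment of class `feature_store`.
#' @export
feature_store <- function() {
  fs <- new.env(parent = emptyenv())
  fs$features <- list()     # "name@version" -> feature_definition
  fs$values <- list()       # "name@version" -> value set
  fs$audit <- list()
  class(fs) <- "feature_store"
  fs
}

#' @export
print.feature_store <- function(x, ...) {
  states <- vapply(x$features, `[[`, "", "state")
  cat(sprintf("<feature_store> %d features (%d deployed, %d quarantined)\n",
              length(states), sum(states == "deployed"), sum(states == "quarantined")))
  invisible(x)
}

feature_key <- function(name, version) paste0(name, "@", version)

#' Register a feature (quarantined until audited)
#'
#' @param fs a [feature_store()].
#' @param definition a [feature_definition()].
#' @return the stored definition, invisibly.
#' @export
register_feature <- function(fs, definition) {
  stopifnot(inherits(fs, "feature_store"), inherits(definition, "feature_definition"))
  key <- feature_key(definition$name, definition$version)
  if (!is.null(fs$features[[key]])) {
    conflict_error(paste0("feature already registered: ", key))
  }
  prev <- Filter(function(f) f$name == definition$name, fs$features)
  if (length(prev) && definition$version <= max(vapply(prev, `[[`, 1L, "version"))) {
    conflict_error("feature version must strictly increase")
  }
  definition$state <- "quarantined"
  fs$features[[key]] <- definition
  fs$audit[[length(fs$audit) + 1L]] <-
    list(event = "registered", feature = key, at = now_stamp())
  invisible(definition)
}

#' Audit a quarantined feature
#'
#' @param fs a [feature_store()].
#' @param name,version the feature.
#' @param auditor the administrator performing the audit.
#' @param approve deploy (`TRUE`) or retire (`FALSE`).
#' @export
audit_feature <- function(fs, name, version = 1L, auditor, approve = TRUE) {
  key <- feature_key(name, version)
  def <- fs$features[[key]]
  if (is.null(def)) not_found_error(paste0("unknown feature: ", key))
  if (def$state != "quarantined") conflict_error("only quarantined features can be audited")
  def$state <- if (approve) "deployed" else "retired"
  fs$features[[key]] <- def
  fs$audit[[length(fs$audit) + 1L]] <-
    list(event = "audited", feature = key, auditor = auditor,
         outcome = def$state, at = now_stamp())
  invisible(def)
}

#' Retire a deployed feature
#'
#' @inheritParams audit_feature
#' @export
retire_feature <- function(fs, name, version = 1L, auditor = "admin") {
  key <- feature_key(name, version)
  def <- fs$features[[key]]
  if (is.null(def)) not_found_error(paste0("unknown feature: ", key))
  if (def$state != "deployed") conflict_error("only deployed features can be retired")
  def$state <- "retired"
  fs$features[[key]] <- def
  fs$audit[[length(fs$audit) + 1L]] <-
    list(event = "retired", feature = key, auditor = auditor, at = now_stamp())
  invisible(def)
}

input_data_version <- function(store) {
  paste0(length(store$batches), ":",
         if (length(store$batch_fingerprints)) {
           substr(sha256_hex(paste(store$batch_fingerprints, collapse = "|")), 1, 12)
         } else "empty")
}

#' Compute a deployed feature against a store
#'
#' Refuses quarantined/retired features. A runtime failure inside the
#' generator marks the feature value set as failed with diagnostics and
#' leaves the store untouched (computation is transactional per feature).
#'
#' @param fs a [feature_store()].
#' @param name,version the feature.
#' @param store an [omop_store()].
#' @return the stored value set: list with `feature`, `level`, `values`
#'   (named), `computed_at`, `input_data_version`, `failed`.
#' @export
compute_feature <- function(fs, name, version = 1L, store) {
  key <- feature_key(name, version)
  def <- fs$features[[key]]
  if (is.null(def)) not_found_error(paste0("unknown feature: ", key))
  if (def$state != "deployed") {
    conflict_error(paste0("feature is ", def$state, ", not deployed; audit required"))
  }
  vals <- tryCatch(def$generator(store), error = function(e) e)
  if (inherits(vals, "error")) {
    vs <- list(feature = key, level = def$level, values = NULL,
               computed_at = now_stamp(), input_data_version = input_data_version(store),
               failed = TRUE, diagnostics = conditionMessage(vals))
  } else {
    vs <- list(feature = key, level = def$level, values = as.list(vals),
               computed_at = now_stamp(), input_data_version = input_data_version(store),
               failed = FALSE, diagnostics = NULL)
  }
  fs$values[[key]] <- vs
  vs
}

#' Recompute features affected by a data update
#'
#' Exactly the deployed features whose declared input tables intersect the
#' batch's written tables are recomputed; all others keep their stored
#' values (staleness is tracked via the input data version).
#'
#' @param fs a [feature_store()].
#' @param store an [omop_store()].
#' @param batch a batch log entry from [ingest()].
#' @return data frame report (`feature`, `recomputed`).
#' @export
on_data_update <- function(fs, store, batch) {
  touched <- names(batch$counts)
  report <- data.frame(feature = character(0), recomputed = logical(0),
                       stringsAsFactors = FALSE)
  if (length(touched) == 0L) return(report)
  for (key in names(fs$features)) {
    def <- fs$features[[key]]
    if (def$state != "deployed") next
    hit <- length(intersect(def$input_tables, touched)) > 0L
    if (hit) compute_feature(fs, def$name, def$version, store)
    report <- rbind(report, data.frame(feature = key, recomputed = hit,
                                       stringsAsFactors = FALSE))
  }
  report
}

#' Wire a feature store to a data store
#'
#' After attaching, every [ingest()] batch triggers [on_data_update()].
#'
#' @param fs a [feature_store()].
#' @param store an [omop_store()].
#' @export
attach_feature_store <- function(fs, store) {
  store$update_hooks[[length(store$update_hooks) + 1L]] <-
    function(batch) on_data_update(fs, store, batch)
  invisible(fs)
}

#' Assemble the feature matrix of one level
#'
#' Rows are the union of value keys over all deployed features of the
#' level (person pseudonyms, or `pseudonym|date` event keys); columns are
#' the deployed features in deterministic (name) order; cells without a
#' value carry `NA`.
#'
#' @param fs a [feature_store()].
#' @param level `"person"`, `"observation"` or `"measurement"`.
#' @return data frame with a `key` column plus one column per feature.
#' @export
build_feature_matrix <- function(fs, level = c("person", "observation", "measurement")) {
  level <- match.arg(level)
  deployed <- Filter(function(f) f$state == "deployed" && f$level == level, fs$features)
  if (length(deployed) == 0L) {
    warning("no deployed features at level ", level, "; matrix is empty")
    return(data.frame(key = character(0), stringsAsFactors = FALSE))
  }
  keys <- sort(names(deployed))
  all_row_keys <- sort(unique(unlist(lapply(keys, function(k) {
    names(fs$values[[k]]$values)
  }))))
  out <- data.frame(key = all_row_keys, stringsAsFactors = FALSE)
  for (k in keys) {
    vals <- fs$values[[k]]$values
    col <- rep(NA_real_, length(all_row_keys))
    if (length(vals)) {
      got <- match(names(vals), all_row_keys)
      col[got] <- unlist(vals, use.names = FALSE)
    }
    out[[fs$features[[k]]$name]] <- col
  }
  out
}

#' Serialize feature values as compact JSON
#'
#' @param fs a [feature_store()].
#' @param name,version the feature.
#' @return JSON string of the stored value set.
#' @export
feature_values_json <- function(fs, name, version = 1L) {
  vs <- fs$values[[feature_key(name, version)]]
  if (is.null(vs)) not_found_error("feature has no computed values")
  as.character(jsonlite::toJSON(vs, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Built-in pulse-pressure feature (measurement level)
#'
#' Pulse pressure = systolic minus diastolic blood pressure, computed per
#' reading by joining the two Measurement components on their shared
#' reading `group_id`; values are keyed `pseudonym|date`.
#'
#' @param author,description metadata for the definition.
#' @return a [feature_definition()].
#' @export
pulse_pressure_feature <- function(author = "data-engineer",
                                   description = "Pulse pressure (systolic - diastolic, mmHg) per daily reading") {
  feature_definition(
    name = "pulse_pressure", level = "measurement",
    input_tables = "Measurement", author = author, description = description,
    generator = function(store) {
      m <- store$tables$Measurement
      sys <- m[m$source_value == "systolic_bp", ]
      dia <- m[m$source_value == "diastolic_bp", ]
      j <- merge(sys[, c("person_pseudonym", "event_date", "group_id", "value_as_number")],
                 dia[, c("group_id", "value_as_number")],
                 by = "group_id", suffixes = c("_sys", "_dia"))
      setNames(j$value_as_number_sys - j$value_as_number_dia,
               paste(j$person_pseudonym, j$event_date, sep = "|"))
    })
}

# ---- model store ------------------------------------------------------------

#' Create a minimal model store
#'
#' Stores externally developed model artifacts as opaque serialized blobs
#' with metadata and the same quarantine/audit gate as the feature store;
#' deployed artifacts can be retrieved byte-exactly and served for
#' prediction.
#'
#' @return an environment of class `model_store`.
#' @export
model_store <- function() {
  ms <- new.env(parent = emptyenv())
  ms$models <- list()   # "id@version" -> list(blob, metadata, state)
  ms$audit <- list()
  class(ms) <- "model_store"
  ms
}

#' Store a model artifact (quarantined)
#'
#' @param ms a [model_store()].
#' @param id,version model identity.
#' @param artifact either a raw vector (stored as-is) or any R object
#'   (serialized).
#' @param metadata named list.
#' @export
store_model <- function(ms, id, version = 1L, artifact, metadata = list()) {
  key <- feature_key(id, version)
  if (!is.null(ms$models[[key]])) conflict_error(paste0("model already stored: ", key))
  blob <- if (is.raw(artifact)) artifact else serialize(artifact, NULL, version = 2L)
  ms$models[[key]] <- list(blob = blob, metadata = metadata, state = "quarantined")
  ms$audit[[length(ms$audit) + 1L]] <- list(event = "stored", model = key, at = now_stamp())
  invisible(key)
}

#' Audit a stored model
#'
#' @inheritParams store_model
#' @param auditor the administrator.
#' @param approve deploy or reject.
#' @export
audit_model <- function(ms, id, version = 1L, auditor, approve = TRUE) {
  key <- feature_key(id, version)
  m <- ms$models[[key]]
  if (is.null(m)) not_found_error(paste0("unknown model: ", key))
  m$state <- if (approve) "deployed" else "quarantined"
  ms$models[[key]] <- m
  ms$audit[[length(ms$audit) + 1L]] <-
    list(event = "audited", model = key, auditor = auditor, outcome = m$state,
         at = now_stamp())
  invisible(m$state)
}

#' Retrieve a stored artifact's bytes
#'
#' @inheritParams store_model
#' @return the stored raw blob (byte-identical to what was stored).
#' @export
retrieve_model <- function(ms, id, version = 1L) {
  key <- feature_key(id, version)
  m <- ms$models[[key]]
  if (is.null(m)) not_found_error(paste0("unknown model: ", key))
  m$blob
}

#' Apply a deployed model to inputs
#'
#' Deserializes the artifact; a function artifact is called on the inputs,
#' anything else is returned as a constant prediction. Quarantined models
#' are refused until audited.
#'
#' @inheritParams store_model
#' @param inputs inputs passed to the model.
#' @export
predict_model <- function(ms, id, version = 1L, inputs) {
  key <- feature_key(id, version)
  m <- ms$models[[key]]
  if (is.null(m)) not_found_error(paste0("unknown model: ", key))
  if (m$state != "deployed") conflict_error("model is quarantined; audit required")
  obj <- unserialize(m$blob)
  if (is.function(obj)) obj(inputs) else obj
}
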