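#' Build a synthetic four-node sharing network
#'
#' Constructs the reference deployment shape: three source nodes — an EMR
#' node (demographics, admissions, diagnoses for every patient), a
#' telehealth node (daily measurements, observations and notes for a
#' subset) and a register-of-deaths node (death dates for a small subset)
#' — all sharing at trust level 4 into one central registry node. All four
#' nodes operate under one aligned PPRL (same trait set, encoding
#' configuration and secret), so the central node consolidates each
#' person's rows under a single central pseudonym while every context
#' keeps its own pseudonym.
#'
#' @param n_patients number of ground-truth persons.
#' @param days telehealth series length in days.
#' @param seed integer seed for all synthetic inputs.
#' @param secret the shared PPRL secret.
#' @param telehealth_fraction,deaths_fraction fractions of persons known
#'   to the telehealth and deaths nodes.
#' @return list with `nodes` (named list of [hds_node()]s: `emr`,
#'   `telehealth`, `deaths`, `central`), `identities` (the ground-truth
#'   [generate_identities()] set), `pseudonyms` (per node: person index ->
#'   source pseudonym, NA where the person is unknown to the node) and
#'   `receipts` of the level-4 pushes.
#' @export
demo_network <- function(n_patients = 20L, days = 5L, seed = 1L,
                         secret = "demo-network-secret",
                         telehealth_fraction = 0.8, deaths_fraction = 0.15) {
  ids <- generate_identities(n_patients, duplicate_rate = 0, seed = seed)
  cfg <- encoding_config()
  mk <- function(ctx) hds_node(ctx, secret, cfg)
  nodes <- list(emr = mk("emr"), telehealth = mk("telehealth"),
                deaths = mk("deaths"), central = mk("central"))

  register_all <- function(node, person_idx) {
    ps <- rep(NA_character_, n_patients)
    for (i in person_idx) {
      ps[i] <- register_identity(node$index, ids$records[[i]], node$context,
                                 node$secret, node$thresholds)$pseudonym
    }
    ps
  }
  n_tele <- max(1L, round(telehealth_fraction * n_patients))
  n_dead <- max(1L, round(deaths_fraction * n_patients))
  idx_tele <- seq_len(n_tele)
  idx_dead <- seq_len(n_dead)
  pseud <- list(emr = register_all(nodes$emr, seq_len(n_patients)),
                telehealth = register_all(nodes$telehealth, idx_tele),
                deaths = register_all(nodes$deaths, idx_dead))

  vmap <- vocabulary_map()
  # EMR payload: demographics + admissions + ICD-10 diagnoses
  emr_payload <- with_seed(seed + 1L, {
    dob <- vapply(ids$records, function(r) r$traits$date_of_birth, character(1))
    adm <- format(as.Date("2023-01-01") + sample.int(300L, n_patients, replace = TRUE),
                  "%Y-%m-%d")
    icd <- c("I50.0", "I50.1", "I50.9", "I25.9", "I48.9", "E11.9")
    list(patients = data.frame(patient_id = sprintf("H%03d", seq_len(n_patients)),
                               gender = sample(c("female", "male"), n_patients, replace = TRUE),
                               year_of_birth = substr(dob, 1, 4),
                               admission_date = adm,
                               discharge_date = format(as.Date(adm) + 7L, "%Y-%m-%d"),
                               stringsAsFactors = FALSE),
         diagnoses = data.frame(patient_id = sprintf("H%03d", seq_len(n_patients)),
                                icd10 = sample(icd, n_patients, replace = TRUE),
                                date = adm, stringsAsFactors = FALSE))
  })
  emr_resolver <- function(pid) pseud$emr[match(pid, sprintf("H%03d", seq_len(n_patients)))]
  ingest(nodes$emr$store, emr_payload, emr_converter(), emr_resolver, vmap)

  tele_ids <- sprintf("T%03d", idx_tele)
  th <- generate_telehealth_export(n_tele, days, seed = seed + 2L, patient_ids = tele_ids)
  tele_resolver <- function(pid) pseud$telehealth[idx_tele[match(pid, tele_ids)]]
  for (conv in list(telehealth_measurements_converter(),
                    telehealth_observations_converter(),
                    telehealth_notes_converter())) {
    ingest(nodes$telehealth$store, th, conv, tele_resolver, vmap)
  }

  deaths_payload <- with_seed(seed + 3L, data.frame(
    patient_id = sprintf("D%03d", idx_dead),
    date_of_death = format(as.Date("2024-06-01") + sample.int(120L, n_dead, replace = TRUE),
                           "%Y-%m-%d"),
    stringsAsFactors = FALSE))
  deaths_resolver <- function(pid) pseud$deaths[idx_dead[match(pid, sprintf("D%03d", idx_dead))]]
  ingest(nodes$deaths$store, deaths_payload, deaths_converter(), deaths_resolver, vmap)

  receipts <- lapply(nodes[c("emr", "telehealth", "deaths")], function(src) {
    set_policy(src, "central", level = 4L)
    push_omop_rows(src, nodes$central)
  })
  list(nodes = nodes, identities = ids, pseudonyms = pseud, receipts = receipts)
}

#' Central pseudonym of a person in a demo network
#'
#' Follows the cross-context links recorded in the central node's person
#' index from a source pseudonym to the central-context pseudonym.
#'
#' @param net a [demo_network()] result.
#' @param source_pseudonym the pseudonym at the source node.
#' @param source_context the source node context.
#' @return the central pseudonym, or `NA` if the person was never shared.
#' @export
central_pseudonym_of <- function(net, source_pseudonym, source_context) {
  resolve_link(net$nodes$central$index, source_pseudonym, source_context, "central")
}
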