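.loc_display <- c(exon19 = "Exon 19", exon20 = "Exon 20", T790M = "T790M",
                  L858R = "L858R", L861Q = "L861Q", G719X = "G719X",
                  S768I = "S768I")

.default_location_weights <- c(exon19 = 536, L858R = 354, G719X = 170,
                               T790M = 149, S768I = 37, L861Q = 27,
                               exon20 = 19) / 1292

#' Configuration for the synthetic report generator
#'
#' Defines the composition of a synthetic corpus of EGFR laboratory reports
#' with known ground truth. The default status mix approximates the southern
#' export's observed proportions (about 74% not detected, 24% identified —
#' of which a quarter at multiple locations — and 1% insufficient DNA, with
#' 1% cancelled tests for the status-extension scenario); the default
#' location weights follow the observed per-location tallies, and the
#' multi-location split follows the observed 2/3/4-location ratios.
#'
#' @param n_reports Number of reports to generate.
#' @param status_mix Named probabilities over `not_detected`, `identified_1`,
#'   `identified_multi`, `insufficient_dna`, `cancelled`; must sum to 1.
#' @param location_weights Named probabilities over the 7 assay locations.
#' @param multi_k_weights Probabilities that a multi-location result carries
#'   2, 3, or 4 locations.
#' @param dialect `"sad"` or `"nad"` column layout.
#' @param rtf_wrap Wrap report bodies in an RTF envelope? Defaults to `TRUE`
#'   for the southern dialect, which stores RTF.
#' @param phrasing_variant_rate Probability of synonym phrasings
#'   ("positive"/"negative" instead of "identified"/"not detected").
#' @param specific_rate Probability that an exon 19 (deletion) or exon 20
#'   (insertion) call spells out its specific result.
#' @param noise_rate Probability of replacing the result sentence with an
#'   out-of-grammar sentence (ground truth then records `unparseable`).
#' @param missing_uli_rate Probability of an empty patient identifier.
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 100L,
                             status_mix = c(not_detected = 0.74,
                                            identified_1 = 0.18,
                                            identified_multi = 0.06,
                                            insufficient_dna = 0.01,
                                            cancelled = 0.01),
                             location_weights = .default_location_weights,
                             multi_k_weights = c(`2` = 257, `3` = 33, `4` = 20) / 310,
                             dialect = c("sad", "nad"),
                             rtf_wrap = NULL,
                             phrasing_variant_rate = 0.2,
                             specific_rate = 0.8,
                             noise_rate = 0,
                             missing_uli_rate = 0.02,
                             seed = 1L) {
  dialect <- match.arg(dialect)
  if (is.null(rtf_wrap)) rtf_wrap <- dialect == "sad"
  check_probs <- function(p, what, names_needed) {
    if (!setequal(names(p), names_needed)) {
      stop(what, " must be named over: ", paste(names_needed, collapse = ", "),
           call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
    p[names_needed]
  }
  status_mix <- check_probs(status_mix, "status_mix",
                            c("not_detected", "identified_1",
                              "identified_multi", "insufficient_dna",
                              "cancelled"))
  location_weights <- check_probs(location_weights, "location_weights",
                                  names(.loc_display))
  multi_k_weights <- check_probs(multi_k_weights, "multi_k_weights",
                                 c("2", "3", "4"))
  stopifnot(n_reports >= 0L,
            phrasing_variant_rate >= 0, phrasing_variant_rate <= 1,
            specific_rate >= 0, specific_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_reports = as.integer(n_reports), status_mix = status_mix,
                 location_weights = location_weights,
                 multi_k_weights = multi_k_weights, dialect = dialect,
                 rtf_wrap = rtf_wrap,
                 phrasing_variant_rate = phrasing_variant_rate,
                 specific_rate = specific_rate, noise_rate = noise_rate,
                 missing_uli_rate = missing_uli_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Render the location phrase for one mutation call, exercising both
# attachment orders the grammar allows (specific before or after location).
.render_loc <- function(location, specific) {
  disp <- .loc_display[[location]]
  if (specific == "none") return(disp)
  word <- if (specific == "deletion") sample(c("deletions", "deletion"), 1L)
          else sample(c("insertions", "insertion"), 1L)
  if (stats::runif(1) < 0.5) paste(word, "in", disp) else paste(disp, word)
}

.render_sentence <- function(status, mutations, variant) {
  if (status == "not_detected") {
    return(if (variant) "The EGFR test was negative."
           else "The EGFR mutation was Not Detected.")
  }
  if (status == "insufficient_dna") {
    return("There was insufficient DNA for the test.")
  }
  if (status == "cancelled") {
    return(if (stats::runif(1) < 0.5) "Test cancelled due to insufficient DNA."
           else "Test cancelled.")
  }
  phrases <- vapply(seq_len(nrow(mutations)), function(i) {
    .render_loc(mutations$location[i], mutations$specific[i])
  }, character(1))
  k <- length(phrases)
  joined <- if (k == 1L) phrases
    else if (k == 2L) paste(phrases[1L], "and", phrases[2L])
    else paste0(paste(phrases[-k], collapse = ", "), " and ", phrases[k])
  verb <- if (k > 1L) "were" else "was"
  if (variant) paste0("The ", joined, " mutation ", verb, " positive.")
  else paste0("The ", joined, " ", verb, " identified.")
}

.noise_sentences <- function(location_weights) {
  loc <- .loc_display[[sample(names(location_weights), 1L,
                              prob = location_weights)]]
  sample(c(paste0("Positive for ", loc, "."),
           paste0(loc, " identified and ", loc, " identified."),
           "Equivocal result, see addendum."), 1L)
}

.sad_body <- function(sentence, low_cellularity) {
  paste(
    "Interpretation and Comments:",
    "See EGFR Mutation Assay below. Testing performed by real-time PCR on",
    "DNA extracted from the submitted specimen.",
    "EGFR Mutation Assay:",
    sentence,
    "Note:",
    "This assay screens hotspot mutations in the EGFR gene and will not",
    "identify alterations outside the targeted regions.",
    "Comment:",
    if (low_cellularity) "Low tumor cellularity noted in this specimen."
    else "None.",
    sep = "\n")
}

.nad_body <- function(sentence) {
  paste("EGFR mutation analysis, tissue.",
        "Result:",
        sentence,
        sep = "\n")
}

#' Generate a synthetic corpus of EGFR laboratory reports
#'
#' Emits a report table in the chosen dialect's column layout together with a
#' long-format ground-truth table, fully reproducible from the seed. Southern
#' (`sad`) reports carry all four section headers and, by default, an RTF
#' envelope around the body; northern (`nad`) reports carry a "Result:"
#' section in a plain `RESULTS` column. Result sentences are rendered from
#' templates covering the general result forms — not detected, identified at
#' one or several locations (joined by "and"/commas, with deletion/insertion
#' specifics attached on either side of the location), insufficient DNA, and
#' cancelled tests — plus synonym phrasings and optional out-of-grammar noise
#' sentences. Comment sections occasionally carry a low-tumor-cellularity
#' remark, which must not affect extraction.
#'
#' @param config A `generator_config`.
#' @return List with `reports` (tibble in dialect layout, including
#'   `RESULT_ID` and `ULI` identifier columns) and `truth` (tibble with
#'   `result_id`, `patient_id`, `status`, `location`, `specific`,
#'   `phrasing`), one truth row per mutation call for identified results and
#'   one row otherwise.
#' @examples
#' corpus <- generate_corpus(generator_config(n_reports = 3, seed = 42))
#' corpus$truth
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, .generate_corpus_impl(config),
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

.generate_corpus_impl <- function(config) {
  n <- config$n_reports
  prefix <- toupper(config$dialect)
  report_rows <- vector("list", max(n, 0L))
  truth_rows <- vector("list", max(n, 0L))

  for (i in seq_len(n)) {
    result_id <- sprintf("%s-%06d", prefix, i)
    uli <- if (stats::runif(1) < config$missing_uli_rate) "" else
      sprintf("%09d", sample.int(999999999L, 1L))
    status <- sample(names(config$status_mix), 1L, prob = config$status_mix)

    mutations <- empty_mutations()
    if (status %in% c("identified_1", "identified_multi")) {
      k <- if (status == "identified_1") 1L else
        as.integer(sample(names(config$multi_k_weights), 1L,
                          prob = config$multi_k_weights))
      locs <- sample(names(config$location_weights), k,
                     prob = config$location_weights)
      spec <- vapply(locs, function(l) {
        if (l == "exon19" && stats::runif(1) < config$specific_rate) "deletion"
        else if (l == "exon20" && stats::runif(1) < config$specific_rate) "insertion"
        else "none"
      }, character(1), USE.NAMES = FALSE)
      mutations <- tibble::tibble(location = locs, specific = spec)
      status <- "identified"
    }

    variant <- stats::runif(1) < config$phrasing_variant_rate
    noisy <- stats::runif(1) < config$noise_rate
    if (noisy) {
      sentence <- .noise_sentences(config$location_weights)
      phrasing <- "noise"
      status <- "unparseable"
      mutations <- empty_mutations()
    } else {
      sentence <- .render_sentence(status, mutations, variant)
      phrasing <- if (variant) "synonym" else "standard"
    }

    low_cell <- stats::runif(1) < 0.03
    if (config$dialect == "sad") {
      body <- .sad_body(sentence, low_cell)
      if (config$rtf_wrap) body <- rtf_wrap(body)
      report_rows[[i]] <- tibble::tibble(
        RESULT_ID = result_id,
        ULI = uli,
        SPECIMEN_ACCN = sprintf("S%02d-%05d", 13L + (i %% 7L), i),
        SPECIMEN_SOURCE = sample(c("lung, right upper lobe",
                                   "lung, left lower lobe",
                                   "lymph node", "pleural fluid"), 1L),
        TEST_NAME = "EGFR Result",
        TEST_TASK = sample(c("EGFR (Interpretation)", "EGFR (Qualitative)"), 1L),
        RTF_RESULT = body,
        RESULT_SHORT = switch(status, identified = "Detected",
                              not_detected = "Not Detected", "TNP"))
    } else {
      report_rows[[i]] <- tibble::tibble(
        RESULT_ID = result_id,
        ULI = uli,
        RESULTS = .nad_body(sentence))
    }

    truth_rows[[i]] <- if (status == "identified") {
      tibble::tibble(result_id = result_id, patient_id = uli, status = status,
                     location = mutations$location,
                     specific = mutations$specific, phrasing = phrasing)
    } else {
      tibble::tibble(result_id = result_id, patient_id = uli, status = status,
                     location = NA_character_, specific = NA_character_,
                     phrasing = phrasing)
    }
  }

  list(reports = dplyr::bind_rows(report_rows),
       truth = dplyr::bind_rows(truth_rows))
}
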