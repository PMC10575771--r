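# Reading, validating and harmonising study-level summary tables.

.regions <- c("MFC", "DLPFC", "frontal_white_matter", "thalamus",
              "temporal_lobe", "basal_ganglia")
.metabolites <- c("glutamate", "glutamine", "Glx")
.med_status <- c("antipsychotic_naive", "medicated", "mixed")
.acquisitions <- c("standard", "j_edited", "epsi")
.ref_schemes <- c("cr_scaled", "csf_corrected", "other")

# versioned voxel-label synonym table; assign_region() is total on this and
# raises on anything else -- no default bucket
.region_synonyms <- c(
  "mfc" = "MFC",
  "medial frontal cortex" = "MFC",
  "medial prefrontal cortex" = "MFC",
  "mpfc" = "MFC",
  "anterior cingulate cortex" = "MFC",
  "anterior cingulate" = "MFC",
  "acc" = "MFC",
  "dlpfc" = "DLPFC",
  "dorsolateral prefrontal cortex" = "DLPFC",
  "frontal white matter" = "frontal_white_matter",
  "fwm" = "frontal_white_matter",
  "thalamus" = "thalamus",
  "temporal lobe" = "temporal_lobe",
  "temporal cortex" = "temporal_lobe",
  "superior temporal gyrus" = "temporal_lobe",
  "stg" = "temporal_lobe",
  "hippocampus" = "temporal_lobe",
  "basal ganglia" = "basal_ganglia",
  "caudate" = "basal_ganglia",
  "putamen" = "basal_ganglia",
  "globus pallidus" = "basal_ganglia",
  "substantia nigra" = "basal_ganglia",
  "striatum" = "basal_ganglia"
)

.mandatory_cols <- c("study_id", "region", "metabolite",
                     "mean_p", "sd_p", "n_p", "mean_c", "sd_c", "n_c")
.moderator_cols <- c("mean_age", "prop_male", "panss_total", "panss_total_sd",
                     "age_sd", "cpz", "snr_ratio", "fwhm_ratio")
.optional_cols <- c("cohort_id", "timepoint", "n_clinical_groups",
                    "medication_status", "acquisition", "reference_scheme",
                    "scale_factor", .moderator_cols)

#' Region synonym table
#'
#' The versioned mapping from free-text voxel labels to the six brain-region
#' categories used throughout the analyses: medial frontal cortex (`MFC`,
#' including medial prefrontal and anterior cingulate voxels), dorsolateral
#' prefrontal cortex (`DLPFC`), frontal white matter, thalamus, temporal lobe
#' (including superior temporal gyrus and hippocampus) and basal ganglia
#' (including caudate, putamen, globus pallidus and substantia nigra).
#'
#' @return Named character vector mapping lower-case labels to region codes.
#' @export
region_synonyms <- function() .region_synonyms

#' Map voxel labels to brain-region categories
#'
#' Deterministic mapping through [region_synonyms()]; labels are matched
#' case-insensitively after trimming whitespace.  Unknown labels raise an
#' error (there is no default bucket), listing the accepted labels.
#'
#' @param voxel_label Character vector of voxel labels (already-canonical
#'   region codes are passed through).
#' @return Character vector of region codes.
#' @examples
#' assign_region(c("anterior cingulate cortex", "hippocampus", "caudate"))
#' @export
assign_region <- function(voxel_label) {
  stopifnot(is.character(voxel_label), all(nzchar(trimws(voxel_label))))
  key <- tolower(trimws(voxel_label))
  out <- ifelse(voxel_label %in% .regions, voxel_label,
                unname(.region_synonyms[key]))
  if (anyNA(out)) {
    bad <- unique(voxel_label[is.na(out)])
    stop("unknown voxel label(s): ", paste(sQuote(bad), collapse = ", "),
         "\nKnown labels: ", paste(names(.region_synonyms), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Rescale metabolite summaries from J-edited or EPSI acquisitions
#'
#' Metabolite estimates from J-edited and echo-planar spectroscopic imaging
#' sequences are reported on much smaller numeric scales and are multiplied
#' by 1000 or 100,000 to obtain values comparable with standard acquisitions.
#' Mean and SD are scaled by the same factor, so all downstream effect sizes
#' (lnCVR, lnVR, Hedges' g) are unchanged.
#'
#' @param mean,sd Numeric summaries to rescale.
#' @param factor Scale factor, 1e3 or 1e5.
#' @param acquisition Acquisition label; must be `"j_edited"` or `"epsi"` --
#'   applying a factor to a standard acquisition is an error.
#' @return List with rescaled `mean` and `sd`.
#' @export
rescale_metabolite <- function(mean, sd, factor, acquisition) {
  if (!all(factor %in% c(1e3, 1e5)))
    stop("scale factor must be 1000 or 100000", call. = FALSE)
  if (any(acquisition == "standard"))
    stop("scale factor applied to a standard-acquisition record", call. = FALSE)
  stopifnot(all(acquisition %in% c("j_edited", "epsi")))
  list(mean = mean * factor, sd = sd * factor)
}

#' Adjust the control sample size for shared control groups
#'
#' When one study reports several clinical groups against a single control
#' group, the control n is divided by the number of clinical groups so that
#' controls are not double-counted across the resulting records.
#'
#' @param n_controls Reported control sample size(s).
#' @param n_clinical_groups Number of clinical groups sharing the controls.
#' @param mode `"fractional"` (default) keeps the fractional quotient, which
#'   the effect-size bias terms handle exactly; `"integer"` rounds half-down
#'   to an integer.
#' @return Numeric effective control n.  Values below 2 make the small-sample
#'   bias term undefined; such records are flagged unusable at validation.
#' @examples
#' adjust_control_n(30, 2)  # 15
#' adjust_control_n(5, 2, mode = "integer")  # 2 (round-half-down)
#' @export
adjust_control_n <- function(n_controls, n_clinical_groups,
                             mode = c("fractional", "integer")) {
  mode <- match.arg(mode)
  stopifnot(all(n_controls >= 1), all(n_clinical_groups >= 1))
  eff <- n_controls / n_clinical_groups
  if (mode == "integer") eff <- ceiling(eff - 0.5)
  eff
}

#' Study-table column dictionary
#'
#' @return Data frame documenting the expected columns, whether each is
#'   mandatory, and its units, as shipped in
#'   `inst/extdata/column_dictionary.tsv`.
#' @export
study_table_schema <- function() {
  path <- system.file("extdata", "column_dictionary.tsv", package = "glumeta")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and validate a study-level summary table
#'
#' Reads a CSV/TSV with one row per study x cohort x brain region x
#' metabolite, validates and harmonises it: region labels are mapped through
#' [assign_region()], J-edited/EPSI records with a `scale_factor` column are
#' rescaled, the control n is adjusted for shared controls, and invalid rows
#' are collected in a rejects table with a reason each -- nothing is dropped
#' silently.
#'
#' @param path File path (or a data frame already in memory).
#' @param sep Field separator; `NULL` (default) picks `\t` for `.tsv`
#'   files and `,` otherwise.
#' @param control_n_mode Passed to [adjust_control_n()].
#' @param timepoint_filter Keep only the first timepoint of longitudinal
#'   studies (default `TRUE`; rows with `timepoint > 1` are rejected with a
#'   reason, mirroring first-timepoint inclusion rules).
#' @return Object of class `study_table`: a list with `records` (validated
#'   data frame), `rejects` (data frame with a `reason` column) and `summary`.
#' @export
read_study_table <- function(path, sep = NULL,
                             control_n_mode = c("fractional", "integer"),
                             timepoint_filter = TRUE) {
  control_n_mode <- match.arg(control_n_mode)
  if (is.data.frame(path)) {
    raw <- path
  } else {
    stopifnot(file.exists(path))
    if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  miss <- setdiff(.mandatory_cols, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  # defaults for optional columns
  if (is.null(raw$cohort_id)) raw$cohort_id <- raw$study_id
  if (is.null(raw$timepoint)) raw$timepoint <- 1L
  if (is.null(raw$n_clinical_groups)) raw$n_clinical_groups <- 1L
  if (is.null(raw$medication_status)) raw$medication_status <- "mixed"
  if (is.null(raw$acquisition)) raw$acquisition <- "standard"
  if (is.null(raw$reference_scheme)) raw$reference_scheme <- "other"
  for (mc in .moderator_cols) if (is.null(raw[[mc]])) raw[[mc]] <- NA_real_

  reasons <- character(nrow(raw))
  num_cols <- c("mean_p", "sd_p", "n_p", "mean_c", "sd_c", "n_c",
                "n_clinical_groups", "timepoint", .moderator_cols)
  for (cn in num_cols) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(conv)
      reasons[bad & reasons == ""] <- paste0("non-numeric ", cn)
      raw[[cn]] <- conv
    }
  }

  # harmonise regions / metabolites (mapping failures become rejects)
  reg <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    reg[i] <- tryCatch(assign_region(as.character(raw$region[i])),
                       error = function(e) NA_character_)
    if (is.na(reg[i]) && reasons[i] == "")
      reasons[i] <- paste0("unknown region label '", raw$region[i], "'")
  }
  raw$region <- reg
  bad_met <- !(raw$metabolite %in% .metabolites)
  reasons[bad_met & reasons == ""] <-
    paste0("unknown metabolite '", raw$metabolite[bad_met], "'")
  bad_med <- !(raw$medication_status %in% .med_status)
  reasons[bad_med & reasons == ""] <- "unknown medication_status"

  # rescaling
  if (!is.null(raw$scale_factor)) {
    sf <- suppressWarnings(as.numeric(raw$scale_factor))
    has_sf <- !is.na(sf) & sf != 1
    bad_sf <- has_sf & raw$acquisition == "standard"
    reasons[bad_sf & reasons == ""] <- "scale factor on standard acquisition"
    do_sf <- has_sf & !bad_sf & reasons == ""
    if (any(do_sf)) {
      sc_p <- rescale_metabolite(raw$mean_p[do_sf], raw$sd_p[do_sf],
                                 sf[do_sf], raw$acquisition[do_sf])
      sc_c <- rescale_metabolite(raw$mean_c[do_sf], raw$sd_c[do_sf],
                                 sf[do_sf], raw$acquisition[do_sf])
      raw$mean_p[do_sf] <- sc_p$mean; raw$sd_p[do_sf] <- sc_p$sd
      raw$mean_c[do_sf] <- sc_c$mean; raw$sd_c[do_sf] <- sc_c$sd
    }
  }

  # shared-control adjustment
  raw$n_c_raw <- raw$n_c
  ok_adj <- reasons == "" & !is.na(raw$n_c) & !is.na(raw$n_clinical_groups) &
    raw$n_c >= 1 & raw$n_clinical_groups >= 1
  raw$n_c[ok_adj] <- adjust_control_n(raw$n_c[ok_adj],
                                      raw$n_clinical_groups[ok_adj],
                                      mode = control_n_mode)

  # invariants
  chk <- function(cond, why) reasons[cond & reasons == ""] <<- why
  chk(is.na(raw$mean_p) | is.na(raw$sd_p) | is.na(raw$n_p) |
      is.na(raw$mean_c) | is.na(raw$sd_c) | is.na(raw$n_c),
      "missing group summary")
  chk(!is.na(raw$sd_p) & raw$sd_p <= 0, "non-positive SD")
  chk(!is.na(raw$sd_c) & raw$sd_c <= 0, "non-positive SD")
  chk(!is.na(raw$mean_p) & raw$mean_p <= 0, "non-positive mean")
  chk(!is.na(raw$mean_c) & raw$mean_c <= 0, "non-positive mean")
  chk(!is.na(raw$n_p) & raw$n_p < 2, "n < 2 makes bias term undefined")
  chk(!is.na(raw$n_c) & raw$n_c < 2,
      "n < 2 makes bias term undefined (after shared-control adjustment)")
  if (timepoint_filter)
    chk(!is.na(raw$timepoint) & raw$timepoint > 1, "later timepoint")
  dup <- duplicated(raw[c("study_id", "cohort_id", "region", "metabolite")])
  chk(dup, "duplicate cohort x region x metabolite record")

  keep <- reasons == ""
  records <- raw[keep, , drop = FALSE]
  rejects <- raw[!keep, , drop = FALSE]
  rejects$reason <- reasons[!keep]
  rownames(records) <- NULL; rownames(rejects) <- NULL

  out <- list(records = records, rejects = rejects,
              summary = list(n_input = nrow(raw), n_valid = nrow(records),
                             n_rejected = nrow(rejects),
                             control_n_mode = control_n_mode))
  class(out) <- "study_table"
  out
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study-level summary table:", x$summary$n_valid, "valid records,",
      x$summary$n_rejected, "rejected\n")
  if (nrow(x$records)) {
    tab <- table(x$records$region, x$records$metabolite)
    print(tab)
  }
  if (nrow(x$rejects)) {
    cat("Reject reasons:\n")
    print(table(x$rejects$reason))
  }
  invisible(x)
}

#' Write validated records back to disk
#'
#' Numeric fields are written with enough precision for a byte-stable
#' round-trip through [read_study_table()].
#'
#' @param records Data frame of validated records (or a `study_table`).
#' @param path Output path; `.tsv` gives tab separation.
#' @export
write_study_table <- function(records, path) {
  if (inherits(records, "study_table")) records <- records$records
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- records
  for (cn in names(df)) if (is.numeric(df[[cn]])) df[[cn]] <- format(df[[cn]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the rejects report and a JSON validation summary
#'
#' @param x A `study_table`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_validation_report <- function(x, dir) {
  stopifnot(inherits(x, "study_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "rejects.tsv")
  utils::write.table(x$rejects, p1, sep = "\t", row.names = FALSE, quote = TRUE)
  p2 <- file.path(dir, "validation_summary.json")
  jsonlite::write_json(x$summary, p2, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p1, p2))
}
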