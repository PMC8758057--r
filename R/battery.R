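#' Item definitions for the symptomatic questionnaire battery
#'
#' Returns the full item battery used throughout the package: the
#' O'Leary-Sant Interstitial Cystitis Symptom and Problem Indices
#' (ICSI/ICPI, 4 items each), the Overactive Bladder Questionnaire short
#' form symptom items (OAB-q 2-6 and 8), the female Genitourinary Pain
#' Index (fGUPI; eight binary pain location/activity items plus seven
#' ordinal items), and the Pelvic Floor Distress Inventory (PFDI-20).
#'
#' Item scales follow the instruments as administered: ICSI items 0-5,
#' ICPI items 0-4, OAB-q items 1-6, fGUPI 1a-1d and 2a-2d binary 0/1,
#' fGUPI 3 on 0-5, fGUPI 4 on 0-10 (pain VAS), fGUPI 5-6 on 0-5,
#' fGUPI 7-8 on 0-3, fGUPI 9 on 0-6, and all PFDI items 0-4.
#'
#' @return A data.frame with one row per item and columns
#'   \code{instrument}, \code{item_id}, \code{scale_min}, \code{scale_max}
#'   and \code{kind} (\code{"ordinal"} or \code{"binary"}).
#' @examples
#' b <- battery_items()
#' table(b$instrument)
#' @export
battery_items <- function() {
  it <- function(instrument, item_id, lo, hi, kind = "ordinal") {
    data.frame(instrument = instrument, item_id = item_id,
               scale_min = lo, scale_max = hi, kind = kind,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    it("ICSI", paste0("icsi_", 1:4), 0L, 5L),
    it("ICPI", paste0("icpi_", 1:4), 0L, 4L),
    it("OABQ", paste0("oabq_", c(2:6, 8)), 1L, 6L),
    it("FGUPI", paste0("fgupi_", c("1a", "1b", "1c", "1d",
                                   "2a", "2b", "2c", "2d")), 0L, 1L, "binary"),
    it("FGUPI", "fgupi_3", 0L, 5L),
    it("FGUPI", "fgupi_4", 0L, 10L),
    it("FGUPI", c("fgupi_5", "fgupi_6"), 0L, 5L),
    it("FGUPI", c("fgupi_7", "fgupi_8"), 0L, 3L),
    it("FGUPI", "fgupi_9", 0L, 6L),
    it("PFDI", sprintf("pfdi_%02d", 1:20), 0L, 4L)
  )
  stopifnot(!anyDuplicated(rows$item_id))
  rownames(rows) <- rows$item_id
  rows
}

#' Item identifiers of the battery, in canonical column order
#' @return Character vector of the 49 item ids.
#' @export
battery_item_ids <- function() battery_items()$item_id

#' Per-phenotype item calibration parameters
#'
#' The per-item group means and standard deviations (ordinal items) and
#' endorsement proportions (binary fGUPI pain-location/activity items)
#' that characterise the three symptomatic bladder-pain phenotypes --
#' myofascial pelvic pain (MFP), bladder-specific pain (BPS) and
#' non-urologic pelvic pain (NUPP) -- together with an asymptomatic
#' control profile. These parameters are the calibration targets for the
#' synthetic cohort generator and double as per-group mean item profiles
#' for worked scoring examples.
#'
#' The control column is a synthetic asymptomatic profile (low endorsement
#' of every symptom); the phenotype columns encode observed per-item group
#' statistics for the three phenotypes. Binary items carry the endorsement
#' proportion in the \code{*_mean} column and \code{NA} in \code{*_sd}
#' (a Bernoulli SD is implied by its mean).
#'
#' @return A data.frame keyed by \code{item_id} with columns
#'   \code{mfp_mean}, \code{mfp_sd}, \code{bps_mean}, \code{bps_sd},
#'   \code{nupp_mean}, \code{nupp_sd}, \code{control_mean},
#'   \code{control_sd}, merged with the scale columns of
#'   \code{\link{battery_items}}.
#' @seealso [generate_cohort()], [phenotype_group_sizes()]
#' @export
phenotype_profiles <- function() {
  b <- battery_items()
  # item_id, mfp mean, mfp sd, bps mean, bps sd, nupp mean, nupp sd
  p <- matrix(c(
    2.98, 1.41, 3.16, 1.48, 1.04, 1.14,   # icsi_1
    4.19, 1.04, 4.29, 0.96, 2.16, 1.37,   # icsi_2
    2.95, 1.36, 1.97, 1.15, 1.10, 1.11,   # icsi_3
    2.13, 1.67, 2.61, 1.48, 1.16, 1.23,   # icsi_4
    3.12, 1.02, 3.33, 0.62, 1.46, 1.14,   # icpi_1
    3.10, 1.08, 2.53, 1.19, 0.92, 1.14,   # icpi_2
    2.84, 0.90, 2.40, 1.20, 0.88, 1.11,   # icpi_3
    3.10, 1.30, 3.05, 1.38, 1.75, 1.46,   # icpi_4
    4.77, 1.38, 4.76, 1.11, 2.33, 1.22,   # oabq_2
    4.19, 1.70, 3.74, 1.62, 1.92, 1.17,   # oabq_3
    3.97, 1.87, 2.05, 1.42, 1.89, 1.26,   # oabq_4
    4.45, 1.69, 3.67, 1.66, 2.02, 1.05,   # oabq_5
    4.55, 1.46, 3.93, 1.53, 2.20, 1.17,   # oabq_6
    3.87, 1.89, 2.59, 1.85, 1.41, 0.97,   # oabq_8
    0.48,   NA, 0.38,   NA, 0.58,   NA,   # fgupi_1a
    0.48,   NA, 0.43,   NA, 0.61,   NA,   # fgupi_1b
    0.43,   NA, 0.47,   NA, 0.55,   NA,   # fgupi_1c
    0.74,   NA, 0.76,   NA, 0.59,   NA,   # fgupi_1d
    0.41,   NA, 0.53,   NA, 0.71,   NA,   # fgupi_2a
    0.54,   NA, 0.63,   NA, 0.64,   NA,   # fgupi_2b
    0.58,   NA, 0.79,   NA, 0.25,   NA,   # fgupi_2c
    0.71,   NA, 0.63,   NA, 0.22,   NA,   # fgupi_2d
    3.90, 1.10, 3.67, 1.13, 2.98, 1.15,   # fgupi_3
    6.39, 1.76, 6.13, 1.52, 2.98, 1.61,   # fgupi_4
    3.37, 1.37, 2.65, 1.67, 1.67, 1.64,   # fgupi_5
    3.60, 1.16, 4.05, 1.02, 2.01, 1.42,   # fgupi_6
    2.29, 0.64, 1.89, 1.04, 1.27, 1.14,   # fgupi_7
    2.65, 0.75, 2.66, 0.61, 2.18, 0.92,   # fgupi_8
    5.32, 0.83, 5.01, 0.97, 4.33, 1.62,   # fgupi_9
    2.81, 1.78, 1.91, 1.67, 1.64, 1.52,   # pfdi_01
    2.83, 1.60, 1.76, 1.60, 1.32, 1.44,   # pfdi_02
    0.76, 1.40, 0.34, 0.87, 0.54, 1.16,   # pfdi_03
    1.58, 1.13, 0.40, 0.92, 0.57, 0.99,   # pfdi_04
    3.39, 1.22, 1.62, 1.57, 1.07, 1.25,   # pfdi_05
    0.87, 0.75, 0.12, 0.59, 0.02, 0.13,   # pfdi_06
    2.26, 1.18, 0.76, 1.13, 1.07, 1.21,   # pfdi_07
    2.32, 1.56, 0.74, 1.09, 1.18, 1.31,   # pfdi_08
    1.03, 1.35, 0.02, 0.13, 0.02, 0.13,   # pfdi_09
    1.56, 1.62, 0.23, 0.66, 0.16, 0.56,   # pfdi_10
    2.03, 1.43, 0.21, 0.69, 0.39, 0.98,   # pfdi_11
    1.29, 1.51, 0.14, 0.43, 0.43, 0.81,   # pfdi_12
    2.75, 1.03, 0.70, 1.08, 0.59, 1.01,   # pfdi_13
    1.37, 1.52, 0.05, 0.30, 0.07, 1.03,   # pfdi_14
    3.05, 1.39, 2.83, 1.22, 1.32, 1.33,   # pfdi_15
    2.60, 1.63, 1.24, 1.48, 0.41, 0.85,   # pfdi_16
    1.98, 1.47, 1.05, 1.33, 1.00, 1.21,   # pfdi_17
    2.46, 1.47, 0.86, 1.22, 0.55, 1.06,   # pfdi_18
    2.02, 1.65, 1.28, 1.46, 0.73, 1.17,   # pfdi_19
    3.05, 1.04, 2.18, 1.59, 1.66, 1.61    # pfdi_20
  ), ncol = 6, byrow = TRUE)
  stopifnot(nrow(p) == nrow(b))
  out <- data.frame(b,
                    mfp_mean = p[, 1], mfp_sd = p[, 2],
                    bps_mean = p[, 3], bps_sd = p[, 4],
                    nupp_mean = p[, 5], nupp_sd = p[, 6],
                    stringsAsFactors = FALSE)
  # synthetic asymptomatic control profile: minimal symptom endorsement
  binary <- out$kind == "binary"
  out$control_mean <- ifelse(binary, 0.05, out$scale_min + 0.3)
  out$control_mean[out$item_id == "fgupi_4"] <- 0.5
  out$control_sd <- ifelse(binary, NA_real_, 0.6)
  rownames(out) <- out$item_id
  out
}

#' Default cohort group sizes and ages
#'
#' Group sizes of the phenotyping study design (145 symptomatic cases in
#' three phenotype groups plus 69 asymptomatic controls) with per-group
#' age distributions (years).
#'
#' @return A data.frame with columns \code{group}, \code{n},
#'   \code{age_mean}, \code{age_sd}.
#' @export
phenotype_group_sizes <- function() {
  data.frame(
    group = c("BPS", "NUPP", "MFP", "CONTROL"),
    n = c(56L, 31L, 58L, 69L),
    age_mean = c(31.53, 37.8, 31.34, 34.1),
    age_sd = c(7.18, 6.3, 19.7, 6.4),
    stringsAsFactors = FALSE
  )
}

#' Default treatment attempt counts and response rates by phenotype
#'
#' Observed responder contingency cells for the four common IC/BPS
#' therapies: oral bladder analgesics, intravesical instillations, pelvic
#' floor physical therapy (PFPT) and amitriptyline. \code{attempted} is
#' the number of subjects in the phenotype who tried the therapy and had
#' adequate follow-up; \code{rate} is the observed responder fraction,
#' used as the Bernoulli response probability by the synthetic
#' treatment-record generator.
#'
#' @return A data.frame with columns \code{phenotype}, \code{therapy},
#'   \code{responded}, \code{attempted}, \code{rate}.
#' @seealso [generate_treatment_records()]
#' @export
treatment_response_rates <- function() {
  ph <- rep(c("BPS", "MFP", "NUPP"), each = 4)
  th <- rep(c("analgesic", "instillation", "pfpt", "amitriptyline"), 3)
  resp <- c(9, 18, 3, 5,    1, 2, 23, 1,    4, 1, 5, 5)
  att  <- c(12, 20, 4, 8,   6, 4, 27, 2,    13, 10, 21, 15)
  data.frame(phenotype = ph, therapy = th, responded = resp,
             attempted = att, rate = resp / att, stringsAsFactors = FALSE)
}

# Internal: per-group mean item profile as a named numeric vector,
# used for worked examples and composite sanity checks.
mean_profile <- function(group = c("MFP", "BPS", "NUPP", "CONTROL")) {
  group <- match.arg(group)
  pp <- phenotype_profiles()
  col <- paste0(tolower(group), "_mean")
  stats::setNames(pp[[col]], pp$item_id)
}
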