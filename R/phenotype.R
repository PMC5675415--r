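#' Phenotype parameters for the synthetic rat
#'
#' A `phenotype_params` object states the behavioural regime the simulator
#' renders: how much time the animal spends rearing on its hind paws, how much
#' it leans on the cage wall, and how its weight is shifted along the lateral
#' (left/right) and antero-posterior (front/hind) axes. Biases are expressed
#' as signed fractions of the paw-borne weight: `lateral_bias = +0.03` means
#' the right paws carry 53% of the paw-borne load (3 percentage points above
#' symmetry) and `ap_bias = +0.05` means the front paws carry 5 points more
#' than the healthy front fraction (about 26% of the paw-borne weight; healthy
#' quadrupeds keep roughly three quarters of their weight on the hind paws).
#'
#' @param day Post-lesion day label, one of `"D0"`, `"D1"`, `"D2"`, `"D3"`,
#'   `"D7"`, `"D10"`, `"D14"`, `"D17"`, `"D21"` (`"D0"` is the pre-operative
#'   baseline).
#' @param condition `"normal"` or `"reactivated"` (tail-hanging reactivation
#'   of the vestibular syndrome, modelled purely as a phenotype switch).
#' @param rearing_rate Expected fraction of session time spent in bipedal
#'   rearing.
#' @param lateral_bias Signed fraction of paw-borne weight shifted to the
#'   right (+) or left (-); bounded to `[-0.5, 0.5]`.
#' @param ap_bias Signed fraction shifted to the front (+) or hind (-);
#'   bounded to `[-0.5, 0.5]`.
#' @param wall_lean_rate Expected fraction of time leaning on the cage wall.
#' @param locomotion_rate Expected fraction of time walking; defaults to 20%
#'   of the time not spent rearing or wall-leaning.
#' @param symptom_set Character vector drawn from
#'   `c("tumbling", "retropulsion", "circling", "bobbing", "head_tilt")`.
#' @return An object of class `phenotype_params`.
#' @seealso [make_phenotype_profile()] for the built-in day presets.
#' @export
phenotype_params <- function(day = "D0", condition = "normal",
                             rearing_rate = 0.38, lateral_bias = 0,
                             ap_bias = 0, wall_lean_rate = 0.10,
                             locomotion_rate = NULL,
                             symptom_set = character(0)) {
  condition <- match.arg(condition, c("normal", "reactivated"))
  stopifnot(
    rearing_rate >= 0, rearing_rate <= 1,
    wall_lean_rate >= 0, wall_lean_rate <= 1,
    rearing_rate + wall_lean_rate <= 1,
    abs(lateral_bias) <= 0.5, abs(ap_bias) <= 0.5
  )
  bad <- setdiff(symptom_set, names(symptom_ratings()))
  if (length(bad)) {
    stop("unknown symptom(s): ", paste(bad, collapse = ", "),
         "; valid symptoms are: ",
         paste(names(symptom_ratings()), collapse = ", "))
  }
  if (is.null(locomotion_rate)) {
    locomotion_rate <- 0.2 * (1 - rearing_rate - wall_lean_rate)
  }
  stopifnot(locomotion_rate >= 0,
            rearing_rate + wall_lean_rate + locomotion_rate <= 1)
  structure(
    list(
      day = day, condition = condition, rearing_rate = rearing_rate,
      lateral_bias = lateral_bias, ap_bias = ap_bias,
      wall_lean_rate = wall_lean_rate, locomotion_rate = locomotion_rate,
      symptom_set = sort(unique(symptom_set))
    ),
    class = "phenotype_params"
  )
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf(
    paste0("<phenotype_params> %s/%s rearing=%.2f wall=%.2f loco=%.2f ",
           "lateral=%+.3f ap=%+.3f symptoms={%s}\n"),
    x$day, x$condition, x$rearing_rate, x$wall_lean_rate, x$locomotion_rate,
    x$lateral_bias, x$ap_bias, paste(x$symptom_set, collapse = ",")
  ))
  invisible(x)
}

#' Valid post-lesion day labels
#' @return Character vector of recognised day labels, in temporal order.
#' @export
dwb_day_labels <- function() {
  c("D0", "D1", "D2", "D3", "D7", "D10", "D14", "D17", "D21")
}

# Day presets encoding the qualitative post-lesion time course:
#  - rearing collapses at D1-D3 and recovers by D7;
#  - weight shifts forward and to the side contralateral (right) to the
#    (left-ear) lesion at D1-D2; the lateral bias reverses to the lesioned
#    (left) side from D7 on;
#  - the syndrome score decays 15 -> 10 -> 6 -> 3 -> 1 over three weeks.
# Rearing rates follow the observed two-paw time fractions (~38% pre-op,
# ~4-8% acutely, ~34% compensated); the D1 biases reproduce the reported
# barycenter displacement (+3.11 points right, +4.83 points front).
day_presets <- function() {
  list(
    D0  = list(rearing = 0.38, wall = 0.10, lat =  0.000, ap = 0.000,
               sym = character(0)),
    D1  = list(rearing = 0.04, wall = 0.05, lat =  0.031, ap = 0.048,
               sym = c("retropulsion", "circling", "bobbing", "head_tilt")),
    D2  = list(rearing = 0.05, wall = 0.05, lat =  0.031, ap = 0.040,
               sym = c("circling", "bobbing", "head_tilt")),
    D3  = list(rearing = 0.08, wall = 0.06, lat =  0.010, ap = 0.000,
               sym = c("circling", "bobbing", "head_tilt")),
    D7  = list(rearing = 0.30, wall = 0.08, lat = -0.020, ap = 0.000,
               sym = c("bobbing", "head_tilt")),
    D10 = list(rearing = 0.33, wall = 0.09, lat = -0.020, ap = 0.000,
               sym = c("bobbing", "head_tilt")),
    D14 = list(rearing = 0.34, wall = 0.10, lat = -0.020, ap = 0.000,
               sym = c("bobbing", "head_tilt")),
    D17 = list(rearing = 0.35, wall = 0.10, lat = -0.020, ap = 0.000,
               sym = "head_tilt"),
    D21 = list(rearing = 0.34, wall = 0.10, lat = -0.020, ap = 0.000,
               sym = c("bobbing", "head_tilt"))
  )
}

#' Built-in lesion phenotype presets by post-lesion day
#'
#' Returns the default [phenotype_params()] encoding the post-lesion time
#' course of a left-ear vestibular neurectomy: suppressed rearing during the
#' acute phase (D1-D3), a transient forward and rightward (contralateral)
#' weight shift at D1-D2, reversal of the lateral bias to the lesioned side
#' from D7, and a shrinking symptom set. Under the `"reactivated"` condition
#' (tail-hanging test) the compensated-phase (D7-D21) rearing rate is halved,
#' re-expressing part of the acute stance phenotype.
#'
#' @param day Day label; see [dwb_day_labels()].
#' @param condition `"normal"` or `"reactivated"`.
#' @return A [phenotype_params()] object.
#' @examples
#' make_phenotype_profile("D1", "normal")
#' @export
make_phenotype_profile <- function(day, condition = c("normal", "reactivated")) {
  condition <- match.arg(condition)
  presets <- day_presets()
  if (length(day) != 1L || !day %in% names(presets)) {
    stop("unknown day label ", deparse(substitute(day)), " (got: ",
         paste(day, collapse = ", "), "); valid labels are: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[day]]
  rearing <- p$rearing
  if (condition == "reactivated" &&
      day %in% c("D7", "D10", "D14", "D17", "D21")) {
    rearing <- rearing / 2
  }
  phenotype_params(
    day = day, condition = condition, rearing_rate = rearing,
    lateral_bias = p$lat, ap_bias = p$ap, wall_lean_rate = p$wall,
    symptom_set = p$sym
  )
}
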