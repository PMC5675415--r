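no_analyzable_time <- function() {
  stop(structure(
    class = c("dwb_no_analyzable_time", "error", "condition"),
    list(message = "no analyzable time: every frame is excluded",
         call = sys.call(-1))
  ))
}

mask_frames <- function(tracks, mask) {
  if (is.null(mask)) return(seq_len(tracks$n_frames))
  stopifnot(length(mask$analyzable) == tracks$n_frames)
  which(mask$analyzable)
}

#' Stance-time fractions
#'
#' Percentage of analyzable time the animal spends on 0, 1, 2, 3 and 4 paws.
#' Per analyzable frame, the stance count is the number of paws (FL, FR, HL,
#' HR) bearing a positive load; tail and belly contacts do not count.
#'
#' @param tracks A `paw_tracks` object (see [link_tracks()]).
#' @param mask An `analyzable_mask`, or `NULL` to use every frame.
#' @return Named numeric vector `c("0", ..., "4")` of percentages summing to
#'   100.
#' @export
stance_time_fractions <- function(tracks, mask = NULL) {
  fr <- mask_frames(tracks, mask)
  if (length(fr) == 0L) no_analyzable_time()
  n_paws <- rowSums(tracks$load[fr, PAW_IDS, drop = FALSE] > 0)
  out <- tabulate(n_paws + 1L, nbins = 5L) / length(fr) * 100
  names(out) <- as.character(0:4)
  out
}

#' Front-paw contact time
#'
#' Percentage of analyzable time each front paw touches the floor.
#'
#' @inheritParams stance_time_fractions
#' @return Named numeric vector `c(FL = , FR = )` of percentages.
#' @export
front_paw_contact_time <- function(tracks, mask = NULL) {
  fr <- mask_frames(tracks, mask)
  if (length(fr) == 0L) no_analyzable_time()
  c(
    FL = mean(tracks$load[fr, "FL"] > 0) * 100,
    FR = mean(tracks$load[fr, "FR"] > 0) * 100
  )
}

# per-paw mean load in g over the analyzable frames in which that paw is in
# contact (the quantity the commercial device reports per paw); 0 for a paw
# never in contact
contact_mean_loads <- function(tracks, frames) {
  vapply(PAW_IDS, function(p) {
    v <- tracks$load[frames, p]
    v <- v[v > 0]
    if (length(v)) mean(v) else 0
  }, numeric(1))
}

#' Weight distribution along the body axes
#'
#' Mean paw load while in contact, as a percentage of the animal's weight on
#' the day of acquisition: front (FL+FR), hind (HL+HR), left (FL+HL) and
#' right (FR+HR). Each paw's load is averaged over the analyzable frames in
#' which that paw touches the floor (the per-paw quantity the acquisition
#' device reports), so front+hind (= left+right) falls slightly below 100
#' when the tail or belly carries load -- healthy rats typically show about
#' 73% hind / 26% front -- and is insensitive to how much time the animal
#' spends rearing.
#'
#' @inheritParams stance_time_fractions
#' @param body_weight Animal weight in g.
#' @return Named numeric vector `c(front, hind, left, right)` of percentages.
#' @export
weight_distribution_axes <- function(tracks, mask = NULL, body_weight) {
  stopifnot(body_weight > 0)
  fr <- mask_frames(tracks, mask)
  if (length(fr) == 0L) no_analyzable_time()
  m <- contact_mean_loads(tracks, fr)
  c(
    front = (m[["FL"]] + m[["FR"]]) / body_weight * 100,
    hind = (m[["HL"]] + m[["HR"]]) / body_weight * 100,
    left = (m[["FL"]] + m[["HL"]]) / body_weight * 100,
    right = (m[["FR"]] + m[["HR"]]) / body_weight * 100
  )
}

#' Barycenter-like weight repartition (PRP / PFP)
#'
#' The two coordinates of the barycenter-like statistic: the percentage of
#' the four-paw-borne weight carried by the right paws,
#' \deqn{PRP = (W_{FRP} + W_{RRP}) / TWP \times 100,}
#' and by the front paws,
#' \deqn{PFP = (W_{FRP} + W_{FLP}) / TWP \times 100,}
#' where the per-paw weights W are aggregated over the analyzable frames and
#' TWP is their four-paw total. Three aggregation conventions are available:
#' `"contact_means"` (default) takes each paw's mean load while in contact --
#' the per-paw quantity the acquisition device reports, and the only reading
#' under which the front/hind percentages of a healthy rearing rat sum to
#' just under 100; `"ratio_of_sums"` sums loads over all analyzable frames
#' before forming the ratios; `"mean_of_ratios"` averages per-frame ratios
#' over frames with positive paw load. All three satisfy the
#' complementarity identities exactly and agree when every paw is loaded in
#' every frame.
#'
#' @inheritParams stance_time_fractions
#' @param method Aggregation convention, see Details.
#' @return Named numeric vector `c(PRP = , PFP = )`, each in `[0, 100]`.
#'   `PRP + PLP = 100` and `PFP + PHP = 100` hold exactly, with PLP and PHP
#'   the left/hind analogues.
#' @examples
#' tr <- structure(list(
#'   load = matrix(rep(c(30, 30, 20, 20, 0, 0), each = 2), 2,
#'                 dimnames = list(NULL, c("FR", "FL", "HR", "HL",
#'                                         "TAIL", "BELLY"))),
#'   intervals = NULL, n_frames = 2L), class = "paw_tracks")
#' barycenter(tr) # PRP 50, PFP 60 for FR=FL=30, HR=HL=20
#' @export
barycenter <- function(tracks, mask = NULL,
                       method = c("contact_means", "ratio_of_sums",
                                  "mean_of_ratios")) {
  method <- match.arg(method)
  fr <- mask_frames(tracks, mask)
  if (length(fr) == 0L) no_analyzable_time()
  L <- tracks$load[fr, PAW_IDS, drop = FALSE]
  if (method %in% c("contact_means", "ratio_of_sums")) {
    W <- if (method == "contact_means") contact_mean_loads(tracks, fr)
         else colSums(L)
    TWP <- sum(W)
    if (TWP <= 0) {
      stop("no paw-borne weight over the analyzable frames")
    }
    PRP <- (W[["FR"]] + W[["HR"]]) / TWP * 100
    PFP <- (W[["FR"]] + W[["FL"]]) / TWP * 100
  } else {
    twp <- rowSums(L)
    ok <- twp > 0
    if (!any(ok)) stop("no paw-borne weight over the analyzable frames")
    PRP <- mean((L[ok, "FR"] + L[ok, "HR"]) / twp[ok]) * 100
    PFP <- mean((L[ok, "FR"] + L[ok, "FL"]) / twp[ok]) * 100
  }
  c(PRP = PRP, PFP = PFP)
}

#' Summarise one session into its outcome metrics
#'
#' Assembles the per-session outcome vector: stance-time fractions,
#' front-paw contact times, axis-wise weight distribution, the PRP/PFP
#' barycenter-like statistic and the analyzed time, plus session metadata.
#' When no frame is analyzable all measures are `NA` and `analyzable` is
#' `FALSE`.
#'
#' @inheritParams weight_distribution_axes
#' @param meta Named list of session metadata; `body_weight` is required
#'   unless passed separately, `animal_id`, `day` and `condition` are carried
#'   through when present.
#' @param barycenter_method Passed to [barycenter()].
#' @return A one-row data.frame of class `session_metrics`.
#' @export
summarize_session <- function(tracks, mask = NULL, meta = list(),
                              body_weight = meta$body_weight,
                              barycenter_method = "contact_means") {
  base <- data.frame(
    animal_id = meta$animal_id %||% NA_character_,
    day = meta$day %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    body_weight = body_weight %||% NA_real_,
    stringsAsFactors = FALSE
  )
  fr <- mask_frames(tracks, mask)
  frame_rate <- if (!is.null(mask)) mask$frame_rate else 30
  if (length(fr) == 0L) {
    out <- cbind(base, data.frame(
      analyzable = FALSE, analyzed_time = 0,
      pct_time_on_0 = NA_real_, pct_time_on_1 = NA_real_,
      pct_time_on_2 = NA_real_, pct_time_on_3 = NA_real_,
      pct_time_on_4 = NA_real_,
      pct_time_FL = NA_real_, pct_time_FR = NA_real_,
      pct_weight_front = NA_real_, pct_weight_hind = NA_real_,
      pct_weight_left = NA_real_, pct_weight_right = NA_real_,
      PRP = NA_real_, PFP = NA_real_
    ))
    class(out) <- c("session_metrics", class(out))
    return(out)
  }
  stopifnot(!is.null(body_weight))
  st <- stance_time_fractions(tracks, mask)
  fp <- front_paw_contact_time(tracks, mask)
  wd <- weight_distribution_axes(tracks, mask, body_weight)
  bc <- barycenter(tracks, mask, method = barycenter_method)
  out <- cbind(base, data.frame(
    analyzable = TRUE,
    analyzed_time = length(fr) / frame_rate,
    pct_time_on_0 = st[["0"]], pct_time_on_1 = st[["1"]],
    pct_time_on_2 = st[["2"]], pct_time_on_3 = st[["3"]],
    pct_time_on_4 = st[["4"]],
    pct_time_FL = fp[["FL"]], pct_time_FR = fp[["FR"]],
    pct_weight_front = wd[["front"]], pct_weight_hind = wd[["hind"]],
    pct_weight_left = wd[["left"]], pct_weight_right = wd[["right"]],
    PRP = bc[["PRP"]], PFP = bc[["PFP"]]
  ))
  class(out) <- c("session_metrics", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run detection, assignment and metrics on one simulated session
#'
#' Convenience pipeline: [detect_session()] -> [assign_session()] ->
#' [build_analyzable_mask()] -> [summarize_session()].
#'
#' @param session A `dwb_session` from [simulate_session()], or a bare
#'   `session_recording`.
#' @param activation_threshold,min_cells Passed to [detect_session()].
#' @param params An [assign_params()].
#' @param barycenter_method Passed to [summarize_session()].
#' @return A list with `metrics` (one-row `session_metrics`), `tracks`,
#'   `mask`, `assignment` and `blobs`.
#' @export
analyze_session <- function(session, activation_threshold = 1,
                            min_cells = 1L, params = assign_params(),
                            barycenter_method = "contact_means") {
  recording <- if (inherits(session, "dwb_session")) session$recording
               else session
  stopifnot(inherits(recording, "session_recording"))
  blobs <- detect_session(recording, activation_threshold, min_cells)
  asg <- assign_session(blobs, recording$n_frames, params)
  mask <- build_analyzable_mask(blobs, recording$n_frames,
                                ambiguous = asg$ambiguous,
                                frame_rate = recording$geometry$frame_rate)
  metrics <- summarize_session(
    asg$tracks, mask, meta = recording$meta,
    barycenter_method = barycenter_method
  )
  list(metrics = metrics, tracks = asg$tracks, mask = mask,
       assignment = asg, blobs = blobs)
}
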