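#' Synthetic per-animal supplementary table (stand-in)
#'
#' The original per-animal spreadsheet of analysed measures is not
#' redistributable, so this function builds a SYNTHETIC stand-in: a
#' per-animal, per-day table whose group means and SEMs equal reference
#' values typical of healthy rats (day `D0`) and of the acute phase after a
#' left unilateral vestibular neurectomy (day `D1`). Within each day x metric
#' cell the per-animal values are the group mean plus a fixed standardised
#' deviation pattern, so recomputing `mean` and `sd/sqrt(n)` recovers the
#' reference values exactly. Use it to exercise [read_supplementary_table()]
#' and [group_summary()]; it carries no information beyond the group
#' statistics it was built from.
#'
#' @param n_animals Number of synthetic animals (default 9).
#' @return Data.frame with columns `animal`, `day` and eight metric columns
#'   (`pct_time_on_4`, `pct_time_on_2`, `pct_time_FL`, `pct_time_FR`,
#'   `pct_weight_front`, `pct_weight_hind`, `pct_weight_left`,
#'   `pct_weight_right`).
#' @export
synthetic_supplementary_data <- function(n_animals = 9L) {
  stopifnot(n_animals >= 3L)
  # reference group means and SEMs per metric: c(mean_D0, sem_D0, mean_D1,
  # sem_D1)
  ref <- list(
    pct_time_on_4    = c(45.8, 6.5, 86.6, 3.2),
    pct_time_on_2    = c(37.7, 5.6, 4.3, 1.6),
    pct_time_FL      = c(53.8, 6.7, 89.1, 1.9),
    pct_time_FR      = c(55.0, 5.7, 86.9, 2.7),
    pct_weight_front = c(25.7, 1.2, 30.8, 0.8),
    pct_weight_hind  = c(72.8, 1.6, 67.4, 1.0),
    pct_weight_left  = c(46.6, 1.7, 42.2, 2.3),
    pct_weight_right = c(49.3, 1.6, 54.2, 2.1)
  )
  z <- as.vector(scale(seq_len(n_animals))) # mean 0, sd exactly 1
  rows <- lapply(c("D0", "D1"), function(day) {
    out <- data.frame(animal = paste0("rat", sprintf("%02d", seq_len(n_animals))),
                      day = day)
    for (m in names(ref)) {
      r <- ref[[m]]
      mu <- if (day == "D0") r[1] else r[3]
      sem <- if (day == "D0") r[2] else r[4]
      out[[m]] <- mu + sem * sqrt(n_animals) * z
    }
    out
  })
  do.call(rbind, rows)
}
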