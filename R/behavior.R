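#' Cylinder-test paw-drag percentage
#'
#' Percentage of paw drags over total paw touches of the affected forelimb
#' during rearing. Trials without touches are undefined and returned as
#' `NA`.
#'
#' @param paw_drags,paw_touches non-negative counts with
#'   `paw_drags <= paw_touches`; vectorized.
#' @return percentage (`NA` where `paw_touches` is 0).
#' @examples
#' paw_drag_percent(6, 30)  # 20
#' @export
paw_drag_percent <- function(paw_drags, paw_touches) {
  if (any(paw_drags < 0) || any(paw_touches < 0))
    stopf("counts must be non-negative")
  if (any(paw_drags > paw_touches))
    stopf("`paw_drags` cannot exceed `paw_touches`")
  out <- 100 * paw_drags / paw_touches
  out[paw_touches == 0] <- NA_real_
  out
}

#' Horizontal-ladder success score and foot-fault rate
#'
#' Skilled forepaw placement is scored per step: a full success (all four
#' digits placed correctly in front of the rung) earns 1 point, a partial
#' success (misplacement of one or more digits or of the palm) 0.5 points,
#' and a complete misplacement with slip (miss) 0 points. The success
#' score is the percentage of points earned out of the maximum possible
#' (one per step); the foot-fault rate is the number of misplacements
#' divided by the total number of steps. By default every non-full step is
#' a misplacement; `misplacement = "miss_only"` counts only misses.
#'
#' @param steps character vector of step categories (`"full"`,
#'   `"partial"`, `"miss"`), one per step taken.
#' @param misplacement `"non_full"` (default) or `"miss_only"`.
#' @return list with `success_percent` and `foot_fault_rate`.
#' @examples
#' ladder_scores(rep(c("full", "partial", "miss"), c(8, 1, 1)))
#' # success 85%, fault rate 0.2
#' @export
ladder_scores <- function(steps, misplacement = c("non_full", "miss_only")) {
  misplacement <- match.arg(misplacement)
  if (length(steps) == 0L) stopf("at least one step is required")
  steps <- as.character(steps)
  bad <- setdiff(unique(steps), c("full", "partial", "miss"))
  if (length(bad))
    stopf("unknown step categories: %s", paste(bad, collapse = ", "))
  points <- c(full = 1, partial = 0.5, miss = 0)[steps]
  faults <- if (misplacement == "non_full") steps != "full"
            else steps == "miss"
  list(success_percent = 100 * sum(points) / length(steps),
       foot_fault_rate = sum(faults) / length(steps))
}

#' Score behavioral trial logs
#'
#' Computes per-trial scores from tidy CSV logs: ladder logs with columns
#' `animal, day, step_id, category` yield success percent and foot-fault
#' rate per animal and day; cylinder logs with columns
#' `animal, day, touches, drags` yield paw-drag percentages.
#'
#' @param path CSV path.
#' @param test `"ladder"` or `"cylinder"`.
#' @param ... passed to [ladder_scores()].
#' @return tidy data.frame of scores per animal and day.
#' @export
score_behavior_log <- function(path, test = c("ladder", "cylinder"), ...) {
  test <- match.arg(test)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (test == "ladder") {
    need <- c("animal", "day", "step_id", "category")
    if (!all(need %in% names(df)))
      stopf("ladder CSV must have columns %s", paste(need, collapse = ", "))
    parts <- split(df, list(df$animal, df$day), drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(s) {
      sc <- ladder_scores(s$category, ...)
      data.frame(animal = s$animal[1], day = s$day[1],
                 success_percent = sc$success_percent,
                 foot_fault_rate = sc$foot_fault_rate)
    }))
  } else {
    need <- c("animal", "day", "touches", "drags")
    if (!all(need %in% names(df)))
      stopf("cylinder CSV must have columns %s", paste(need, collapse = ", "))
    out <- data.frame(animal = df$animal, day = df$day,
                      paw_drag_percent = paw_drag_percent(df$drags,
                                                          df$touches))
  }
  rownames(out) <- NULL
  out
}
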