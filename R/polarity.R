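# Per-cell polarity-spot time budgets: latency from cytokinesis to the
# first polarity spot, and time spent with 0/1/2/3 spots between the first
# spot and budding.

#' Per-cell polarity quantities from one trace table
#'
#' For each mother cell: the polarization latency
#' `t_fs_c = (first_spot_frame - cytokinesis_frame) * frame_interval`
#' (minutes), and the total time spent with k = 0, 1, 2, 3 polarity spots
#' over the half-open frame window `[first_spot_frame, bud_frame)`. Spot
#' counts above 3 are clamped to 3 with a warning (the scoring scheme
#' records at most three spots). Cells without an observed first spot are
#' censored: their latency and budgets are NA and they only contribute to
#' censoring counts downstream.
#'
#' @param traces Tibble as returned by [gen_polarity_traces()]: one row per
#'   cell with `cell_id`, `frame_interval`, `cytokinesis_frame`,
#'   `first_spot_frame`, `bud_frame`, `spot_counts` (list-column covering
#'   frames `first_spot_frame .. bud_frame - 1`).
#' @return A tibble with one row per cell: `cell_id`, `censored`, `t_fs_c`,
#'   and `time_0_spots` .. `time_3_spots` (minutes).
#' @export
#' @examples
#' tr <- gen_polarity_traces(synth_config(seed = 1), "wild_type", 5)
#' summarize_trace(tr)
summarize_trace <- function(traces) {
  d <- as_tibble(traces)
  need <- c("cell_id", "frame_interval", "cytokinesis_frame",
            "first_spot_frame", "bud_frame", "spot_counts")
  stopifnot(all(need %in% names(d)))
  rows <- map(seq_len(nrow(d)), function(i) {
    iv <- d$frame_interval[i]
    fs <- d$first_spot_frame[i]
    bud <- d$bud_frame[i]
    if (is.na(fs) || is.na(bud)) {
      return(tibble(cell_id = d$cell_id[i], censored = TRUE,
                    t_fs_c = NA_real_, time_0_spots = NA_real_,
                    time_1_spots = NA_real_, time_2_spots = NA_real_,
                    time_3_spots = NA_real_))
    }
    if (!(d$cytokinesis_frame[i] <= fs && fs <= bud)) {
      abort(paste0("cell ", d$cell_id[i],
                   ": frames must satisfy cytokinesis <= first spot <= bud"))
    }
    counts <- d$spot_counts[[i]]
    if (length(counts) != bud - fs) {
      abort(paste0("cell ", d$cell_id[i],
                   ": spot_counts must cover frames [first spot, bud)"))
    }
    if (any(counts > 3)) {
      warn(paste0("cell ", d$cell_id[i], ": spot counts > 3 clamped to 3"))
      counts <- pmin(counts, 3L)
    }
    if (any(counts < 0)) abort("spot counts must be >= 0")
    budget <- vapply(0:3, function(k) iv * sum(counts == k), numeric(1))
    tibble(cell_id = d$cell_id[i], censored = FALSE,
           t_fs_c = iv * (fs - d$cytokinesis_frame[i]),
           time_0_spots = budget[1], time_1_spots = budget[2],
           time_2_spots = budget[3], time_3_spots = budget[4])
  })
  list_rbind(rows)
}

#' Cohort-level polarity summary
#'
#' Arithmetic means of the per-cell quantities over non-censored cells;
#' censored cells (no observed first spot / bud) are counted separately and
#' never enter the averages.
#'
#' @param traces A trace tibble (see [summarize_trace()]), or the per-cell
#'   summary it returns.
#' @return A one-row tibble: `n_cells`, `n_censored`, `mean_t_fs_c`, and
#'   `mean_time_k_spots` for k = 0..3 (minutes).
#' @export
summarize_cohort <- function(traces) {
  per_cell <- if ("spot_counts" %in% names(traces)) {
    summarize_trace(traces)
  } else {
    as_tibble(traces)
  }
  ok <- filter(per_cell, !.data$censored)
  if (nrow(ok) == 0) abort("all cells are censored: no polarity quantities defined")
  tibble(
    n_cells = nrow(ok),
    n_censored = sum(per_cell$censored),
    mean_t_fs_c = mean(ok$t_fs_c),
    mean_time_0_spots = mean(ok$time_0_spots),
    mean_time_1_spots = mean(ok$time_1_spots),
    mean_time_2_spots = mean(ok$time_2_spots),
    mean_time_3_spots = mean(ok$time_3_spots)
  )
}

#' Probability of polarizing within a time window
#'
#' Fraction of cells that polarized successfully — first spot through bud
#' observed — within `window_min` minutes of cytokinesis.
#'
#' @param traces A trace tibble (see [summarize_trace()]).
#' @param window_min Observation window in minutes (default 500).
#' @return A one-row tibble: `n`, `n_polarized`, `p_polarize`.
#' @export
#' @examples
#' tr <- gen_polarity_traces(synth_config(seed = 1), "wild_type", 41)
#' polarization_probability(tr)$p_polarize # 1
polarization_probability <- function(traces, window_min = 500) {
  if (window_min <= 0) abort("window_min must be > 0")
  d <- as_tibble(traces)
  ok <- !is.na(d$bud_frame) &
    (d$bud_frame - d$cytokinesis_frame) * d$frame_interval <= window_min
  tibble(n = nrow(d), n_polarized = sum(ok),
         p_polarize = if (nrow(d) > 0) mean(ok) else 0)
}
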