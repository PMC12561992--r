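#' Read a network model from its tabular fixture
#'
#' `species.tsv` columns: `id`, `ymax`, `y0`, `tau_class`, `tau`,
#' `compartment` (plus free annotation columns); `reactions.tsv` columns:
#' `id`, `rule`, `W`, `n`, `EC50`. Rules use the Netflux-style grammar of
#' [parse_rule()].
#'
#' @param species_path,reactions_path paths to the TSV tables.
#' @inheritParams network_spec
#' @return a `fen_network`.
#' @export
read_network <- function(species_path, reactions_path,
                         variant = c("disease", "healthy")) {
  sp <- utils::read.delim(species_path, stringsAsFactors = FALSE)
  rx <- utils::read.delim(reactions_path, stringsAsFactors = FALSE)
  need_sp <- c("id", "ymax", "y0", "tau_class", "tau", "compartment")
  if (!all(need_sp %in% names(sp))) {
    stop("species table must have columns: ", paste(need_sp, collapse = ", "))
  }
  need_rx <- c("id", "rule", "W", "n", "EC50")
  if (!all(need_rx %in% names(rx))) {
    stop("reactions table must have columns: ", paste(need_rx, collapse = ", "))
  }
  network_spec(sp, rx, variant = match.arg(variant))
}

#' Write a network model to tabular fixtures
#'
#' Round-trip stable with [read_network()].
#'
#' @param net a `fen_network`.
#' @inheritParams read_network
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, species_path, reactions_path) {
  stopifnot(inherits(net, "fen_network"))
  utils::write.table(net$species, species_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rx <- net$reactions[setdiff(names(net$reactions), "target")]
  utils::write.table(rx, reactions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(species_path, reactions_path))
}

#' Read a glucose fixture (interval CSV plus JSON header)
#'
#' @param intervals_path CSV with columns `t_start_h`, `t_end_h`,
#'   `mean_mmol_l`, `sd_mmol_l`.
#' @param meta_path JSON header with `slope` and `intercept` (optional;
#'   defaults used when absent).
#' @inheritParams glucose_schedule
#' @return a `glucose_schedule`.
#' @export
read_glucose_fixture <- function(intervals_path, meta_path = NULL,
                                 t_end = NULL) {
  iv <- utils::read.csv(intervals_path)
  slope <- 0.051; intercept <- -9.38
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$slope)) slope <- meta$slope
    if (!is.null(meta$intercept)) intercept <- meta$intercept
  }
  glucose_schedule(iv, slope = slope, intercept = intercept, t_end = t_end)
}

#' Write a trajectory as long-format CSV
#'
#' Columns `time_h`, `species`, `activity` (structure outputs appear as the
#' pseudo-species `yNumber` and `yDiameter`).
#'
#' @param traj a `fen_trajectory` or `fen_structure` data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  vars <- setdiff(names(df), "time")
  long <- data.frame(
    time_h = rep(df$time, times = length(vars)),
    species = rep(vars, each = nrow(df)),
    activity = unlist(df[vars], use.names = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
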