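#' Fishing-effort summaries
#'
#' Total hooks set within groups (year, month, fleet, or any combination
#' of logbook columns); group totals always conserve the grand total.
#'
#' @param records cleaned logbook data.frame.
#' @param by character vector of grouping columns.
#' @return data.frame with the grouping columns, `hooks` (total) and
#'   `n_sets`.
#' @export
effort_summary <- function(records, by = "year") {
  assert_logbook(records)
  missing_cols <- setdiff(by, names(records))
  if (length(missing_cols)) {
    stop_config("grouping column(s) not in records: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    out <- records[, by, drop = FALSE]
    out$hooks <- numeric(0)
    out$n_sets <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(records$hooks, records[by], sum)
  names(agg)[ncol(agg)] <- "hooks"
  cnt <- stats::aggregate(records$hooks, records[by], length)
  agg$n_sets <- cnt$x
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Ratio of shark landings to total landings
#'
#' Weight of blue sharks and shortfin makos combined over the weight of
#' all retained species (sharks plus tunas/swordfish/other), per group.
#' Groups with no landed weight at all are reported as missing, not zero.
#'
#' @param records cleaned logbook data.frame with weights.
#' @param by grouping columns (default year by fleet).
#' @return data.frame with the grouping columns, `shark_kg`, `total_kg`
#'   and `ratio` in `[0, 1]` (NA when `total_kg` is 0).
#' @export
shark_ratio <- function(records, by = c("year", "fleet")) {
  assert_logbook(records)
  w <- c("weight_blue", "weight_mako", "weight_other")
  if (any(unlist(records[w]) < 0, na.rm = TRUE)) {
    stop_config("weights must be non-negative")
  }
  shark <- records$weight_blue + records$weight_mako
  total <- shark + records$weight_other
  if (nrow(records) == 0L) {
    out <- records[, by, drop = FALSE]
    out$shark_kg <- out$total_kg <- out$ratio <- numeric(0)
    return(out)
  }
  agg <- stats::aggregate(cbind(shark_kg = shark, total_kg = total),
                          records[by], sum)
  agg$ratio <- ifelse(agg$total_kg > 0, agg$shark_kg / agg$total_kg, NA_real_)
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Species composition of shark landings by numbers and weight
#'
#' Per grouping cell, each species' share of retained shark numbers
#' (`pct_N`) and retained shark weight (`pct_W`); shares sum to 100
#' within every cell.
#'
#' @param records cleaned logbook data.frame.
#' @param by grouping columns (default none: overall composition).
#' @param species species labels with `count_`/`weight_` columns.
#' @return data.frame with the grouping columns, `species`, `n_sharks`,
#'   `weight_kg`, `pct_N`, `pct_W`.
#' @export
composition <- function(records, by = character(0),
                        species = c("blue", "mako")) {
  assert_logbook(records)
  if (nrow(records) == 0L) {
    return(data.frame(species = character(0), n_sharks = numeric(0),
                      weight_kg = numeric(0), pct_N = numeric(0),
                      pct_W = numeric(0)))
  }
  groups <- if (length(by)) records[by] else
    list(all = rep.int("all", nrow(records)))
  pieces <- lapply(species, function(sp) {
    agg <- stats::aggregate(
      cbind(n_sharks = records[[paste0("count_", sp)]],
            weight_kg = records[[paste0("weight_", sp)]]),
      groups, sum)
    agg$species <- sp
    agg
  })
  out <- do.call(rbind, pieces)
  keys <- if (length(by)) by else "all"
  cell <- interaction(out[keys], drop = TRUE)
  out$pct_N <- 100 * out$n_sharks / stats::ave(out$n_sharks, cell, FUN = sum)
  out$pct_W <- 100 * out$weight_kg / stats::ave(out$weight_kg, cell, FUN = sum)
  if (!length(by)) out$all <- NULL
  cols <- c(by, "species", "n_sharks", "weight_kg", "pct_N", "pct_W")
  out <- out[, cols, drop = FALSE]
  out[do.call(order, out[c(by, "species")]), , drop = FALSE]
}
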