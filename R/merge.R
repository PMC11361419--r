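status_tokens <- c("Threatened", "NonThreatened", "NoCall")

check_calls <- function(x, arg) {
  bad <- setdiff(unique(as.character(x)), status_tokens)
  if (length(bad)) {
    abort(paste0("Invalid call token(s) in `", arg, "`: ", paste(bad, collapse = ", ")),
          class = "riskfill_schema_error")
  }
  as.character(x)
}

#' Merge the two algorithms' consensus calls
#'
#' `merge_calls()` combines, species by species, the random-forest and
#' network consensus calls under one of two rules.
#'
#' `mode = "complementary"` (the three-branch rule): (1) both algorithms
#' agree on a status — assign it; (2) exactly one algorithm made a call —
#' assign that call; (3) the calls conflict — leave the species `DDNE`.
#' Two `NoCall`s also leave `DDNE`. `mode = "strict"` assigns a status only
#' when both algorithms made the same call; everything else stays `DDNE`.
#'
#' Both rules are symmetric in their two arguments, and the strict rule's
#' non-DDNE assignments are always a subset of the complementary rule's.
#'
#' @param call_rf,call_ann Character vectors over
#'   `c("Threatened", "NonThreatened", "NoCall")`.
#' @param mode `"complementary"` or `"strict"`.
#' @return Character vector over `c("Threatened", "NonThreatened", "DDNE")`.
#' @examples
#' merge_calls("Threatened", "NoCall")                  # "Threatened"
#' merge_calls("Threatened", "NoCall", mode = "strict") # "DDNE"
#' @export
merge_calls <- function(call_rf, call_ann, mode = c("complementary", "strict")) {
  mode <- match.arg(mode)
  a <- check_calls(call_rf, "call_rf")
  b <- check_calls(call_ann, "call_ann")
  if (mode == "complementary") {
    dplyr::case_when(
      a == b & a != "NoCall" ~ a,
      a == "NoCall" & b != "NoCall" ~ b,
      b == "NoCall" & a != "NoCall" ~ a,
      .default = "DDNE"
    )
  } else {
    dplyr::case_when(a == b & a != "NoCall" ~ a, .default = "DDNE")
  }
}

#' Final status table after gap-filling
#'
#' Species already assessed (status `Threatened` or `NonThreatened`) keep
#' their status; DDNE species receive the merged prediction (possibly
#' remaining `DDNE`). Species excluded upstream (e.g. too many missing
#' traits) can be listed in `unpredictable` and stay `DDNE`.
#'
#' @param status_before Tibble `species_id`, `status` over
#'   `c("Threatened", "NonThreatened", "DDNE")`.
#' @param votes_rf,votes_ann `vote_table`s from [consensus_predict()] for
#'   the DDNE species (missing species are treated as `NoCall`).
#' @param mode Merge rule, see [merge_calls()].
#' @param unpredictable Species ids forced to stay `DDNE`.
#' @return A `final_status` tibble: `species_id`, `status_before`,
#'   `call_rf`, `call_ann`, `status_after`, `merge_mode`.
#' @export
finalize_status <- function(status_before, votes_rf, votes_ann,
                            mode = c("complementary", "strict"),
                            unpredictable = character(0)) {
  mode <- match.arg(mode)
  tb <- dplyr::transmute(status_before,
                         species_id = .data$species_id,
                         status_before = .data$status)
  pick <- function(v) {
    dplyr::select(tibble::as_tibble(v), "species_id", call = "call")
  }
  tb <- dplyr::left_join(tb, dplyr::rename(pick(votes_rf), call_rf = "call"),
                         by = "species_id")
  tb <- dplyr::left_join(tb, dplyr::rename(pick(votes_ann), call_ann = "call"),
                         by = "species_id")
  tb$call_rf <- dplyr::coalesce(tb$call_rf, "NoCall")
  tb$call_ann <- dplyr::coalesce(tb$call_ann, "NoCall")
  merged <- merge_calls(tb$call_rf, tb$call_ann, mode = mode)
  tb$status_after <- dplyr::case_when(
    tb$status_before != "DDNE" ~ tb$status_before,
    tb$species_id %in% unpredictable ~ "DDNE",
    .default = merged
  )
  tb$merge_mode <- mode
  structure(tb, class = c("final_status", class(tb)))
}

#' Status transition summary
#'
#' Tallies species per category before and after gap-filling and derives
#' the headline percentages: the per-category percent change
#' `100 * (after - before) / before` and each category's share of the total
#' pool `100 * count / total`, before and after.
#'
#' @param before,after Either character status vectors (same species
#'   universe, same order not required for vectors of one species each — use
#'   tibbles for explicit alignment), tibbles with `species_id` and a
#'   status column, or named counts per category.
#' @param total_pool Optional pool size for the share denominators
#'   (defaults to the summed counts).
#' @return A `transition_summary` tibble: `status`, `n_before`, `n_after`,
#'   `pct_change`, `share_before`, `share_after`. Counts in both columns
#'   sum to the pool size.
#' @examples
#' transition_summary(c(Threatened = 334, NonThreatened = 7750, DDNE = 4992),
#'                    c(Threatened = 1671, NonThreatened = 10451, DDNE = 1073))
#' @export
transition_summary <- function(before, after, total_pool = NULL) {
  is_count_input <- function(x) is.numeric(x) && !is.null(names(x))
  counts <- function(x, arg) {
    if (is_count_input(x)) return(x)
    if (is.data.frame(x)) {
      st <- if ("status_after" %in% names(x) && identical(arg, "after")) {
        x$status_after
      } else if ("status_before" %in% names(x) && identical(arg, "before")) {
        x$status_before
      } else x$status
      x <- st
    }
    table(factor(x, levels = c("Threatened", "NonThreatened", "DDNE")))
  }
  nb <- counts(before, "before"); na_ <- counts(after, "after")
  cats <- union(names(nb), names(na_))
  nb <- nb[cats]; na_ <- na_[cats]
  nb[is.na(nb)] <- 0; na_[is.na(na_)] <- 0
  # species-universe inputs must reconcile; bare printed tallies from
  # different accounting stages are allowed to differ in total
  if (!(is_count_input(before) && is_count_input(after)) && sum(nb) != sum(na_)) {
    abort("Before/after tallies cover different pool sizes.",
          class = "riskfill_reconciliation_error")
  }
  total <- total_pool %||% sum(nb)
  out <- tibble::tibble(
    status = cats,
    n_before = as.numeric(nb),
    n_after = as.numeric(na_),
    pct_change = ifelse(n_before > 0, 100 * (n_after - n_before) / n_before, NA_real_),
    share_before = 100 * n_before / total,
    share_after = 100 * n_after / total
  )
  structure(out, total = total, class = c("transition_summary", class(out)))
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary> pool of", attr(x, "total"), "species\n")
  df <- dplyr::mutate(tibble::as_tibble(x),
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1)))
  print(df)
  invisible(x)
}
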