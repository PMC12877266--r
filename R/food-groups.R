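#' Default food-group map
#'
#' Maps item-level FFQ intakes (g/d) to analysis food groups. Dairy items carry
#' subtype flags: `fermented` (yogurt, cheese vs. milk, cream, butter,
#' desserts), `fullfat` (full-fat vs. low-fat variants) and `sugary` (cream,
#' desserts and flavored yogurt). `fermented`/`fullfat` each partition the
#' dairy items; `sugary` is an independent flag, so a flavored yogurt counts in
#' both the fermented and the sugary subtype. Butter is treated as
#' non-fermented full-fat dairy. Non-dairy items map to a single group and
#' carry `NA` flags.
#'
#' The map ships as editable YAML in `inst/extdata/food_group_map.yaml`; this
#' function returns the same table.
#'
#' @return A tibble with columns `item`, `group`, `fermented`, `fullfat`,
#'   `sugary`.
#' @seealso [aggregate_food_groups()], [read_food_group_map()]
#' @export
default_food_group_map <- function() {
  dairy <- tibble::tribble(
    ~item,             ~fermented, ~fullfat, ~sugary,
    "milk_full",        FALSE,      TRUE,     FALSE,
    "milk_skim",        FALSE,      FALSE,    FALSE,
    "yogurt_plain",     TRUE,       TRUE,     FALSE,
    "yogurt_flavored",  TRUE,       TRUE,     TRUE,
    "cheese_regular",   TRUE,       TRUE,     FALSE,
    "cheese_lowfat",    TRUE,       FALSE,    FALSE,
    "cream",            FALSE,      TRUE,     TRUE,
    "butter",           FALSE,      TRUE,     FALSE,
    "dessert_sugary",   FALSE,      TRUE,     TRUE,
    "dessert_lowfat",   FALSE,      FALSE,    TRUE
  )
  dairy$group <- "dairy"
  other <- tibble::tibble(
    item = c(
      "vegetables", "fruits", "fish_seafood", "meat", "eggs", "grains",
      "alcohol", "sugary_processed", "high_fat"
    ),
    fermented = NA, fullfat = NA, sugary = NA
  )
  other$group <- other$item
  dplyr::bind_rows(dairy, other)[, c("item", "group", "fermented", "fullfat", "sugary")]
}

#' Read / write a food-group map as YAML
#'
#' @param path file path.
#' @param map a food-group map tibble (see [default_food_group_map()]).
#' @return `read_food_group_map()` returns the map tibble;
#'   `write_food_group_map()` returns `path` invisibly.
#' @export
read_food_group_map <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- purrr::map_dfr(raw, function(x) {
    tibble::tibble(
      item = x$item, group = x$group,
      fermented = x$fermented %||% NA,
      fullfat = x$fullfat %||% NA,
      sugary = x$sugary %||% NA
    )
  })
  validate_food_group_map(map)
  map
}

#' @rdname read_food_group_map
#' @export
write_food_group_map <- function(map, path) {
  validate_food_group_map(map)
  rows <- purrr::pmap(map, function(item, group, fermented, fullfat, sugary) {
    out <- list(item = item, group = group)
    if (!is.na(fermented)) out$fermented <- fermented
    if (!is.na(fullfat)) out$fullfat <- fullfat
    if (!is.na(sugary)) out$sugary <- sugary
    out
  })
  yaml::write_yaml(rows, path)
  invisible(path)
}

validate_food_group_map <- function(map) {
  assert_cols(map, c("item", "group", "fermented", "fullfat", "sugary"),
    "food-group map")
  if (anyDuplicated(map$item) > 0) {
    abort_validation(sprintf(
      "food-group map lists item(s) more than once: %s",
      paste(unique(map$item[duplicated(map$item)]), collapse = ", ")
    ))
  }
  dairy <- map[map$group == "dairy", ]
  if (any(is.na(dairy$fermented)) || any(is.na(dairy$fullfat))) {
    abort_validation(
      "every dairy item needs non-missing fermented and fullfat flags")
  }
  invisible(map)
}

# Names of the dairy exposure columns produced by aggregation.
dairy_group_names <- function() {
  c("dairy_total", "dairy_fermented", "dairy_nonfermented",
    "dairy_fullfat", "dairy_lowfat", "dairy_sugary")
}

#' Aggregate item-level intakes into food groups
#'
#' Sums item intakes (g/d) into analysis food groups. Dairy items are
#' additionally rolled up into total dairy and the fermented / non-fermented,
#' full-fat / low-fat and sugary subtypes. Fermented and non-fermented totals
#' partition total dairy exactly, as do full-fat and low-fat.
#'
#' @param item_intakes tibble with one row per participant: an id column plus
#'   one numeric column per item (g/d, nonnegative). Every non-id column must
#'   appear in the map; an unmapped column is a hard error naming the item.
#' @param map food-group map (default [default_food_group_map()]).
#' @param id name of the id column (default `"participant_id"`).
#' @return tibble: id column, one column per non-dairy group present, and the
#'   six dairy aggregates (`dairy_total`, `dairy_fermented`,
#'   `dairy_nonfermented`, `dairy_fullfat`, `dairy_lowfat`, `dairy_sugary`).
#' @export
aggregate_food_groups <- function(item_intakes, map = default_food_group_map(),
                                  id = "participant_id") {
  validate_food_group_map(map)
  assert_cols(item_intakes, id, "item intake table")
  item_cols <- setdiff(names(item_intakes), id)
  unmapped <- setdiff(item_cols, map$item)
  if (length(unmapped) > 0) {
    abort_validation(sprintf(
      "unmapped item%s in intake table: %s",
      if (length(unmapped) > 1) "s" else "", paste(unmapped, collapse = ", ")
    ))
  }
  vals <- as.matrix(item_intakes[, item_cols, drop = FALSE])
  if (!is.numeric(vals)) abort_validation("item intakes must be numeric")
  if (any(is.na(vals)) || any(vals < 0)) {
    abort_validation("item intakes must be nonnegative and non-missing")
  }
  m <- map[match(item_cols, map$item), ]
  sum_items <- function(keep) {
    if (!any(keep)) return(rep(0, nrow(vals)))
    rowSums(vals[, keep, drop = FALSE])
  }
  out <- tibble::tibble(!!id := item_intakes[[id]])
  for (g in setdiff(unique(m$group), "dairy")) {
    out[[g]] <- sum_items(m$group == g)
  }
  is_dairy <- m$group == "dairy"
  out$dairy_total <- sum_items(is_dairy)
  out$dairy_fermented <- sum_items(is_dairy & m$fermented %in% TRUE)
  out$dairy_nonfermented <- sum_items(is_dairy & m$fermented %in% FALSE)
  out$dairy_fullfat <- sum_items(is_dairy & m$fullfat %in% TRUE)
  out$dairy_lowfat <- sum_items(is_dairy & m$fullfat %in% FALSE)
  out$dairy_sugary <- sum_items(is_dairy & m$sugary %in% TRUE)
  out
}

#' Append food-group columns to a cohort table
#'
#' Convenience wrapper: aggregates whichever mapped item columns are present in
#' `cohort` and joins the group totals back on.
#'
#' @inheritParams aggregate_food_groups
#' @param cohort a cohort tibble with item intake columns.
#' @return `cohort` with the group columns added (existing columns of the same
#'   name are replaced).
#' @export
add_food_groups <- function(cohort, map = default_food_group_map(),
                            id = "participant_id") {
  items <- intersect(map$item, names(cohort))
  if (length(items) == 0) {
    abort_validation("cohort contains no mapped item intake columns")
  }
  groups <- aggregate_food_groups(cohort[, c(id, items)], map = map, id = id)
  cohort <- cohort[, setdiff(names(cohort), setdiff(names(groups), id))]
  dplyr::left_join(cohort, groups, by = id)
}
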