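#' Categorical response panels
#'
#' A `response_panel` holds item responses for N respondents at T occasions
#' on J categorical items, with missing cells coded `NA`.  Category codes
#' are 1-based internally: a response to item j is an integer in
#' `1..n_categories[j]`.  All occasions share the same item set and
#' category counts, so the panel is a rectangular N x T x J array.
#' Attrition (a respondent missing an entire later occasion) is retained,
#' not dropped: latent-chain models marginalize over the missing waves.
#'
#' @param responses integer array of dimension `c(N, T, J)` (respondent,
#'   occasion, item); `NA` marks missing cells.
#' @param n_categories integer vector of length J giving the number of
#'   response categories per item, or a single integer recycled to J.
#' @param items optional character vector of item names (length J).
#' @param covariates optional data frame of per-respondent numeric
#'   covariates (N rows).
#' @param group optional per-respondent grouping factor (length N).
#' @param ids optional respondent identifiers (length N).
#'
#' @return An object of class `response_panel`.
#' @export
response_panel <- function(responses, n_categories, items = NULL,
                           covariates = NULL, group = NULL, ids = NULL) {
  if (!is.array(responses) || length(dim(responses)) != 3L)
    stop("`responses` must be a 3-d array (respondent x occasion x item)")
  storage.mode(responses) <- "integer"
  n <- dim(responses)[1L]; t_occ <- dim(responses)[2L]; j <- dim(responses)[3L]
  if (n < 1L || t_occ < 1L || j < 1L)
    stop("panel needs N >= 1, T >= 1, J >= 1")
  n_categories <- as.integer(rep_len(n_categories, j))
  if (any(n_categories < 2L))
    stop("each item needs at least 2 categories")
  if (is.null(items)) items <- paste0("item", seq_len(j))
  if (length(items) != j) stop("`items` must have length J")
  bad <- which(!is.na(responses) &
                 (responses < 1L |
                    responses > rep(n_categories, each = n * t_occ)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(responses))
    stop(sprintf(
      "response code out of range 1..%d at respondent %d, occasion %d, item '%s' (%d cells total)",
      n_categories[idx[3L]], idx[1L], idx[2L], items[idx[3L]], length(bad)))
  }
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("`ids` must have length N")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("`covariates` must have N rows")
  }
  if (!is.null(group)) {
    group <- as.factor(group)
    if (length(group) != n) stop("`group` must have length N")
  }
  dimnames(responses) <- list(NULL, paste0("t", seq_len(t_occ)), items)
  structure(
    list(responses = responses, n_categories = n_categories, items = items,
         covariates = covariates, group = group, ids = ids),
    class = "response_panel")
}

#' @export
print.response_panel <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("Response panel: %d respondents x %d occasions x %d items\n",
              d[1L], d[2L], d[3L]))
  cat("  categories per item:", paste(x$n_categories, collapse = ", "), "\n")
  miss <- mean(is.na(x$responses))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.response_panel <- function(x) dim(x$responses)

n_respondents <- function(panel) dim(panel$responses)[1L]
n_occasions   <- function(panel) dim(panel$responses)[2L]
n_items       <- function(panel) dim(panel$responses)[3L]

#' Panel file layout
#'
#' Describes how the columns of a delimited file map onto a panel.  The
#' canonical layout is wide: one row per respondent and one column per
#' (item, occasion) pair named by `column_pattern` (default
#' `"{item}_t{occasion}"`).  A long layout has one row per
#' (respondent, occasion, item) and is pivoted to wide on read.
#'
#' @param items character vector of item base names.
#' @param occasions number of occasions T.
#' @param n_categories categories per item (scalar or length-J vector).
#' @param column_pattern glue-style pattern with `{item}` and `{occasion}`
#'   placeholders used to build (and parse) wide column names.
#' @param levels optional list (per item) or vector of raw category labels
#'   in category order; raw values are matched against it and recoded to
#'   `1..C`.  `NULL` means the file already uses codes `1..C`.
#' @param id,covariates,group optional column names.
#' @param missing character vector of raw values treated as missing in
#'   addition to empty cells (default `c("", "NA")`).
#' @param format `"wide"` or `"long"`; long layouts also need
#'   `long_columns = c(occasion=, item=, response=)` naming those columns.
#' @param long_columns named character vector for long files.
#'
#' @return A `panel_layout` list.
#' @export
panel_layout <- function(items, occasions, n_categories,
                         column_pattern = "{item}_t{occasion}",
                         levels = NULL, id = NULL, covariates = NULL,
                         group = NULL, missing = c("", "NA"),
                         format = c("wide", "long"),
                         long_columns = c(occasion = "occasion",
                                          item = "item",
                                          response = "response")) {
  format <- match.arg(format)
  if (format == "long" && is.null(id))
    stop("long layouts require an `id` column")
  structure(
    list(items = as.character(items), occasions = as.integer(occasions),
         n_categories = as.integer(rep_len(n_categories, length(items))),
         column_pattern = column_pattern, levels = levels, id = id,
         covariates = covariates, group = group, missing = missing,
         format = format, long_columns = long_columns),
    class = "panel_layout")
}

#' Read a panel layout from a YAML or JSON config file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top-level
#'   keys are the arguments of [panel_layout()].
#' @return A `panel_layout`.
#' @export
read_layout <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML layouts requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(panel_layout, cfg)
}

wide_column <- function(pattern, item, occasion) {
  out <- gsub("{item}", item, pattern, fixed = TRUE)
  gsub("{occasion}", occasion, out, fixed = TRUE)
}

recode_raw <- function(raw, levels_j, n_cat, missing, where) {
  raw <- as.character(raw)
  raw[raw %in% missing | is.na(raw)] <- NA
  if (is.null(levels_j)) {
    code <- suppressWarnings(as.integer(raw))
    bad <- which(!is.na(raw) & (is.na(code) | code < 1L | code > n_cat))
  } else {
    code <- match(raw, as.character(levels_j))
    bad <- which(!is.na(raw) & is.na(code))
  }
  if (length(bad))
    stop(sprintf(
      "invalid response '%s' in column '%s', row %d (%d invalid cells); declared categories: %s",
      raw[bad[1L]], where, bad[1L], length(bad),
      paste(if (is.null(levels_j)) seq_len(n_cat) else levels_j,
            collapse = ", ")))
  code
}

#' Read a categorical panel from a delimited file
#'
#' @param file path to a CSV/TSV file with a header row.
#' @param layout a [panel_layout()] (or path to a YAML/JSON layout file).
#' @param sep field separator; `NULL` guesses from the file extension.
#' @return A validated [response_panel()].  Respondent order follows file
#'   order (wide) or first appearance of each id (long).
#' @export
read_panel <- function(file, layout, sep = NULL) {
  if (is.character(layout)) layout <- read_layout(layout)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  if (layout$format == "long") raw <- pivot_long_to_wide(raw, layout)
  j <- length(layout$items); t_occ <- layout$occasions
  n <- nrow(raw)
  arr <- array(NA_integer_, dim = c(n, t_occ, j))
  for (tt in seq_len(t_occ)) for (jj in seq_len(j)) {
    col <- wide_column(layout$column_pattern, layout$items[jj], tt)
    if (!col %in% names(raw))
      stop(sprintf("layout names column '%s' but the file does not contain it", col))
    lev <- if (is.list(layout$levels)) layout$levels[[jj]] else layout$levels
    arr[, tt, jj] <- recode_raw(raw[[col]], lev, layout$n_categories[jj],
                                layout$missing, col)
  }
  covariates <- NULL
  if (!is.null(layout$covariates)) {
    miss_cols <- setdiff(layout$covariates, names(raw))
    if (length(miss_cols))
      stop("unknown covariate column(s): ", paste(miss_cols, collapse = ", "))
    covariates <- as.data.frame(
      lapply(raw[layout$covariates], function(v) {
        v[v %in% layout$missing] <- NA
        as.numeric(v)
      }))
  }
  group <- NULL
  if (!is.null(layout$group)) {
    if (!layout$group %in% names(raw))
      stop("unknown group column: ", layout$group)
    group <- raw[[layout$group]]
  }
  ids <- if (!is.null(layout$id)) {
    if (!layout$id %in% names(raw)) stop("unknown id column: ", layout$id)
    raw[[layout$id]]
  } else NULL
  response_panel(arr, layout$n_categories, items = layout$items,
                 covariates = covariates, group = group, ids = ids)
}

pivot_long_to_wide <- function(raw, layout) {
  lc <- layout$long_columns
  need <- c(layout$id, lc[["occasion"]], lc[["item"]], lc[["response"]])
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("long file lacks column(s): ", paste(miss, collapse = ", "))
  ids <- unique(raw[[layout$id]])
  wide <- data.frame(row.names = seq_along(ids), check.names = FALSE)
  wide[[layout$id]] <- ids
  for (tt in seq_len(layout$occasions)) for (item in layout$items) {
    col <- wide_column(layout$column_pattern, item, tt)
    sel <- raw[[lc[["occasion"]]]] == as.character(tt) &
      raw[[lc[["item"]]]] == item
    vals <- rep(NA_character_, length(ids))
    vals[match(raw[[layout$id]][sel], ids)] <- raw[[lc[["response"]]]][sel]
    wide[[col]] <- vals
  }
  keep <- c(layout$covariates, layout$group)
  for (col in keep) {
    if (!col %in% names(raw)) next
    vals <- rep(NA_character_, length(ids))
    first <- !duplicated(raw[[layout$id]])
    vals[match(raw[[layout$id]][first], ids)] <- raw[[col]][first]
    wide[[col]] <- vals
  }
  wide
}

#' Write a panel to a wide CSV file
#'
#' Columns follow the layout's `column_pattern` (default
#' `"{item}_t{occasion}"`); missing cells are written empty.  Reading the
#' file back with the matching layout reproduces the data cells exactly.
#'
#' @param panel a [response_panel()].
#' @param file output path.
#' @param column_pattern wide column naming pattern.
#' @return `file`, invisibly.
#' @export
write_panel <- function(panel, file, column_pattern = "{item}_t{occasion}") {
  out <- data.frame(id = panel$ids, check.names = FALSE)
  for (tt in seq_len(n_occasions(panel)))
    for (jj in seq_len(n_items(panel))) {
      col <- wide_column(column_pattern, panel$items[jj], tt)
      out[[col]] <- panel$responses[, tt, jj]
    }
  if (!is.null(panel$covariates))
    for (cv in names(panel$covariates)) out[[cv]] <- panel$covariates[[cv]]
  if (!is.null(panel$group)) out[["group"]] <- as.character(panel$group)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Merge response categories
#'
#' Recodes each item's categories through a merge map, e.g. collapsing a
#' 4-point concern scale into a binary no/yes indicator with
#' `c(1, 1, 2, 2)`.  The map must be a surjection onto `1..C_new` so no
#' new category index is skipped.  Missing responses stay missing.
#'
#' @param panel a [response_panel()].
#' @param mapping an integer vector (applied to every item) or a list of
#'   per-item integer vectors; `mapping[[j]][old]` is the new code.
#' @return The recoded [response_panel()] with updated category counts.
#' @export
collapse_categories <- function(panel, mapping) {
  j <- n_items(panel)
  if (!is.list(mapping)) mapping <- rep(list(as.integer(mapping)), j)
  if (length(mapping) != j) stop("`mapping` must cover all items")
  new_counts <- integer(j)
  arr <- panel$responses
  for (jj in seq_len(j)) {
    m <- as.integer(mapping[[jj]])
    cj <- panel$n_categories[jj]
    if (length(m) != cj)
      stop(sprintf("mapping for item '%s' must have length %d",
                   panel$items[jj], cj))
    k <- max(m)
    if (any(m < 1L) || !setequal(unique(m), seq_len(k)))
      stop(sprintf("mapping for item '%s' must be a surjection onto 1..%d",
                   panel$items[jj], k))
    new_counts[jj] <- k
    slice <- arr[, , jj]
    slice[!is.na(slice)] <- m[slice[!is.na(slice)]]
    arr[, , jj] <- slice
  }
  response_panel(arr, pmax(new_counts, 2L), items = panel$items,
                 covariates = panel$covariates, group = panel$group,
                 ids = panel$ids)
}

#' Marginal response proportions per item and occasion
#'
#' Proportions are computed over non-missing responses only.  An item with
#' no observed responses at an occasion gets `NA` proportions and is listed
#' in the `"undefined"` attribute rather than silently reported as zero.
#'
#' @param panel a [response_panel()].
#' @return A data frame with columns `item`, `occasion`, `category`,
#'   `proportion` and `n_obs` (non-missing responses for that
#'   item-occasion); proportions sum to 1 within each item-occasion.
#' @export
marginal_proportions <- function(panel) {
  rows <- list(); undefined <- character(0)
  for (jj in seq_len(n_items(panel))) {
    cj <- panel$n_categories[jj]
    for (tt in seq_len(n_occasions(panel))) {
      v <- panel$responses[, tt, jj]
      n_obs <- sum(!is.na(v))
      counts <- tabulate(v, nbins = cj)
      prop <- if (n_obs > 0L) counts / n_obs else rep(NA_real_, cj)
      if (n_obs == 0L)
        undefined <- c(undefined,
                       sprintf("%s @ occasion %d", panel$items[jj], tt))
      rows[[length(rows) + 1L]] <- data.frame(
        item = panel$items[jj], occasion = tt, category = seq_len(cj),
        proportion = prop, n_obs = n_obs)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "undefined") <- undefined
  out
}

#' Response-pattern frequency tables
#'
#' Tabulates the distinct observed joint response vectors and their
#' frequencies.  Missing markers are preserved, so two respondents with the
#' same observed values but different missingness form different patterns.
#' `W` is the number of possible *complete* response cells:
#' `prod(C_j)` for a single occasion and `prod(C_j)^T` for the joint table
#' (e.g. six binary items over three occasions give `(2^6)^3 = 262144`).
#'
#' @param panel a [response_panel()].
#' @param scope `"joint"` (all occasions, the LTA contingency table) or
#'   `"occasion"` (one occasion's cross-section, the LCA table).
#' @param occasion which occasion when `scope = "occasion"`.
#' @return A `pattern_table`: list with `patterns` (P x (T*J) integer
#'   matrix, `NA` preserved), `freq` (counts summing to N), `W`,
#'   `n_categories` (per column), `n_items`, `n_occasions`, `items`, and
#'   `respondent_pattern` (which pattern each respondent carries).
#' @export
pattern_frequencies <- function(panel, scope = c("joint", "occasion"),
                                occasion = 1L) {
  scope <- match.arg(scope)
  if (scope == "joint") {
    t_use <- seq_len(n_occasions(panel))
  } else {
    stopifnot(occasion >= 1L, occasion <= n_occasions(panel))
    t_use <- as.integer(occasion)
  }
  j <- n_items(panel)
  flat <- matrix(panel$responses[, t_use, , drop = FALSE],
                 nrow = n_respondents(panel))
  # column order: item varies fastest within occasion
  flat <- flat[, as.vector(t(matrix(seq_len(length(t_use) * j),
                                    nrow = length(t_use)))), drop = FALSE]
  key <- apply(flat, 1L, function(r) paste(ifelse(is.na(r), ".", r),
                                           collapse = "|"))
  first <- !duplicated(key)
  patterns <- flat[first, , drop = FALSE]
  idx <- match(key, key[first])
  freq <- as.integer(tabulate(idx, nbins = sum(first)))
  w <- prod(panel$n_categories)^length(t_use)
  structure(
    list(patterns = patterns, freq = freq, W = w,
         n_categories = rep(panel$n_categories, times = length(t_use)),
         item_categories = panel$n_categories,
         n_items = j, n_occasions = length(t_use), items = panel$items,
         respondent_pattern = idx, N = n_respondents(panel)),
    class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf(
    "Pattern table: %d distinct patterns over %d occasions x %d items (N = %d, W = %s)\n",
    nrow(x$patterns), x$n_occasions, x$n_items, x$N,
    format(x$W, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

pattern_strings <- function(pt, sep = "") {
  apply(pt$patterns, 1L,
        function(r) paste(ifelse(is.na(r), ".", r), collapse = sep))
}

#' Write a pattern table as a two-column CSV
#'
#' @param pt a `pattern_table`.
#' @param file output path; columns `pattern` (codes concatenated, missing
#'   as `.`) and `frequency`.
#' @return `file`, invisibly.
#' @export
write_pattern_table <- function(pt, file) {
  utils::write.csv(
    data.frame(pattern = pattern_strings(pt), frequency = pt$freq),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# missingness mask id per pattern (strata for the saturated reference)
pattern_masks <- function(pt) {
  apply(is.na(pt$patterns), 1L, function(m) paste(as.integer(m), collapse = ""))
}
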