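#' Normalize a metabolite name for matching
#'
#' Canonical form used for module-membership matching: lower case, Unicode
#' dash/minus variants unified then hyphens stripped, italics markers
#' (`*`) removed, Greek letters spelled out, and all whitespace removed
#' (so hyphen/space/solid spelling variants of the same name coincide).
#' Matching downstream is exact on this form -- no fuzzy matching.
#'
#' @param x character vector of metabolite names.
#' @return normalized character vector.
#' @examples
#' normalize_metabolite_name("Cyanidin 3,5−di−O−hexoside")
#' @export
normalize_metabolite_name <- function(x) {
  x <- tolower(x)
  # unify unicode dashes/minus signs, then strip hyphens entirely
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("-", "", x, fixed = TRUE)
  x <- gsub("*", "", x, fixed = TRUE)
  greek <- c("α" = "alpha", "β" = "beta", "γ" = "gamma",
             "δ" = "delta", "ε" = "epsilon")
  for (g in names(greek)) x <- gsub(g, greek[[g]], x, fixed = TRUE)
  x <- gsub("\\s+", "", x)
  x
}

#' Load the bundled metabolic-module fixtures
#'
#' The package ships membership tables for the two germination-related
#' metabolic modules: the ornithine-asparagine-polyamine module (15
#' members: ornithine, L-asparagine, Asn + 2hexoside and twelve
#' putrescine/spermidine/agmatine-family polyamines) and the
#' shikimate-aromatic-flavonoid module (14 members: shikimic acid,
#' tyrosine, phenylalanine, four tryptophan derivatives and seven
#' flavonoids, of which cyanidin 3,5-di-O-hexoside is the consumption
#' exception). Each member carries its expected trajectory direction
#' (`accumulation`, `consumption` or `special`). Members whose published
#' names are not unambiguously transcribable ship as placeholders flagged
#' `legible = FALSE` rather than guesses; the module cardinalities
#' (15 + 14 = 29) are asserted at load time.
#'
#' @param path optional path to a user-supplied module table in the same
#'   schema (`module`, `member`, `expected_direction`, optional
#'   `legible`); cardinalities are only asserted for the bundled file.
#' @return tibble with columns `module`, `member`, `expected_direction`,
#'   `legible` and the normalized matching key `member_key`.
#' @export
load_module_fixtures <- function(path = NULL) {
  bundled <- is.null(path)
  path <- path %||% system.file("extdata", "metabolic_modules.csv",
                                package = "germscreen", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("module", "member", "expected_direction")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("module table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$legible)) tab$legible <- TRUE
  tab$member_key <- normalize_metabolite_name(tab$member)
  if (anyDuplicated(tab$member_key))
    stop("duplicate member after name normalization: ",
         tab$member[duplicated(tab$member_key)][1])
  if (bundled) {
    counts <- table(tab$module)
    stopifnot(
      counts[["ornithine-asparagine-polyamine"]] == 15L,
      counts[["shikimate-aromatic-flavonoid"]] == 14L,
      nrow(tab) == 29L)
  }
  tibble::as_tibble(tab)
}

#' Load the candidate-class taxonomy fixture
#'
#' Per-compound-class counts of the canonical 74-candidate screen of this
#' design, bundled as a versioned CSV. The counts sum to 74.
#'
#' @return tibble with `compound_class`, `count`.
#' @export
load_candidate_classes <- function() {
  path <- system.file("extdata", "candidate_class_counts.csv",
                      package = "germscreen", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
}

#' Annotate candidate metabolites with module membership
#'
#' Tags each candidate with the metabolic module it belongs to (or none),
#' by exact matching of normalized names (see
#' [normalize_metabolite_name()]). A candidate matching entries in two
#' modules is an error. Fixture members not matched by any candidate are
#' reported in `attr(, "unmatched_members")`.
#'
#' @param candidates character vector of candidate metabolite names, or a
#'   data frame with a `name` column (and optionally `metabolite_id`).
#' @param fixtures module table from [load_module_fixtures()].
#' @return tibble with `candidate`, `module`, `matched_member`,
#'   `expected_direction` (`module = "none"` for unmatched candidates).
#' @export
annotate_modules <- function(candidates, fixtures = load_module_fixtures()) {
  if (is.data.frame(candidates)) {
    ids <- candidates$metabolite_id %||% candidates$name
    nms <- candidates$name %||% ids
  } else {
    ids <- nms <- as.character(candidates)
  }
  keys <- normalize_metabolite_name(nms)
  hit <- lapply(keys, function(k) which(fixtures$member_key == k))
  multi <- vapply(hit, function(h)
    length(unique(fixtures$module[h])) > 1, logical(1))
  if (any(multi))
    stop("ambiguous match: candidate '", nms[multi][1],
         "' matches entries in more than one module")
  idx <- vapply(hit, function(h) if (length(h)) h[1] else NA_integer_,
                integer(1))
  out <- tibble::tibble(
    candidate = nms,
    metabolite_id = ids,
    module = ifelse(is.na(idx), "none", fixtures$module[idx]),
    matched_member = ifelse(is.na(idx), NA_character_,
                            fixtures$member[idx]),
    expected_direction = ifelse(is.na(idx), NA_character_,
                                fixtures$expected_direction[idx]))
  matched <- stats::na.omit(out$matched_member)
  attr(out, "unmatched_members") <-
    fixtures[!(fixtures$member %in% matched),
             c("module", "member", "legible")]
  out
}

#' Per-module direction consistency of observed patterns
#'
#' Counts, per module, the annotated members whose observed trajectory
#' pattern matches the module's expected direction. A member counts as
#' consistent only if every variety's observed label equals the expected
#' direction; members with expected direction `"special"` are excluded
#' from the consistency denominator, and members absent from the pattern
#' table are counted as unevaluated, not mismatched.
#'
#' @param annotated result of [annotate_modules()].
#' @param patterns result of [classify_patterns()] (columns
#'   `metabolite_id`, `variety`, `label`).
#' @return tibble per module: `module`, `n_members`, `n_evaluated`,
#'   `n_consistent`, `consistency` (fraction of evaluated, non-special
#'   members that match).
#' @export
module_direction_summary <- function(annotated, patterns) {
  ann <- annotated[annotated$module != "none", , drop = FALSE]
  mods <- unique(ann$module)
  rows <- lapply(mods, function(mod) {
    mm <- ann[ann$module == mod, ]
    evaluated <- 0L
    consistent <- 0L
    for (i in seq_len(nrow(mm))) {
      labs <- patterns$label[patterns$metabolite_id == mm$metabolite_id[i]]
      if (!length(labs) || mm$expected_direction[i] == "special") next
      evaluated <- evaluated + 1L
      if (all(labs == mm$expected_direction[i]))
        consistent <- consistent + 1L
    }
    tibble::tibble(module = mod, n_members = nrow(mm),
                   n_evaluated = evaluated, n_consistent = consistent,
                   consistency = if (evaluated) consistent / evaluated
                                 else NA_real_)
  })
  do.call(rbind, rows) %||%
    tibble::tibble(module = character(), n_members = integer(),
                   n_evaluated = integer(), n_consistent = integer(),
                   consistency = numeric())
}
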