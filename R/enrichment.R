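#' Hypergeometric over-representation of called genes in gene sets
#'
#' For each gene set, `total` is the number of members present in the
#' universe and `changed` the number of those also called; the one-sided
#' p-value is the hypergeometric upper tail
#' `P(X >= changed)` for X ~ Hypergeometric(|universe|, total, |called|) —
#' the probability of drawing at least `changed` annotated genes when
#' sampling `|called|` genes from the universe without replacement.
#' Output rows mirror the familiar "Changed/Total genes" + p-value layout
#' of GO over-representation reports.
#'
#' @param called character vector of called gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all genes eligible to be called
#'   (typically the genes surviving all filters, i.e. the SAM input).
#' @param sets a `gene_set_collection`.
#' @param adjust add a Benjamini-Hochberg `adjusted_p` column.
#' @return data frame sorted by p: `set_id`, `description`, `changed`,
#'   `total`, `p_value` (and optionally `adjusted_p`). Sets with no member
#'   in the universe are omitted.
#' @export
hypergeometric_enrichment <- function(called, universe, sets,
                                      adjust = FALSE) {
  called <- unique(called)
  universe <- unique(universe)
  stray <- setdiff(called, universe)
  if (length(stray))
    stop("called genes not in universe: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ..." else "", call. = FALSE)
  n_univ <- length(universe)
  n_called <- length(called)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$members, universe)
    total <- length(members)
    if (total == 0L) return(NULL)
    changed <- length(intersect(members, called))
    # P(X >= changed); phyper's lower.tail=FALSE gives P(X > q)
    p <- stats::phyper(changed - 1, total, n_univ - total, n_called,
                       lower.tail = FALSE)
    data.frame(set_id = id, description = sets[[id]]$description,
               changed = changed, total = total, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_id = character(0), description = character(0),
                      changed = integer(0), total = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (adjust && nrow(out) > 0)
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category summary of called genes with direction
#'
#' Counts, for each category, the called genes mapping to it and their
#' up/down split (the bar-chart summary of a DE gene list clustered into
#' functional groups). A gene belonging to several categories is counted
#' once in each; genes in no category are tallied under `"unclassified"`.
#'
#' @param called data frame with columns `gene_id` and `direction`
#'   (`"up"`/`"down"`), e.g. the `called` component of a `sam_result`.
#' @param category_map named list: category -> character vector of gene ids.
#' @return data frame: `category`, `n_total`, `n_up`, `n_down`.
#' @export
summarize_categories <- function(called, category_map) {
  cats <- names(category_map)
  rows <- lapply(cats, function(cat) {
    hit <- called$gene_id %in% category_map[[cat]]
    data.frame(category = cat, n_total = sum(hit),
               n_up = sum(hit & called$direction == "up"),
               n_down = sum(hit & called$direction == "down"),
               stringsAsFactors = FALSE)
  })
  mapped <- unique(unlist(category_map, use.names = FALSE))
  un <- !(called$gene_id %in% mapped)
  rows[[length(rows) + 1L]] <- data.frame(
    category = "unclassified", n_total = sum(un),
    n_up = sum(un & called$direction == "up"),
    n_down = sum(un & called$direction == "down"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
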