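# Decision-rule layer: render a CART tree as "if conditions then outcome"
# rules (one per leaf), apply them, and summarize them for interpretation.

#' Extract decision rules from a CART model
#'
#' Walks every root-to-leaf path and records its conditions. Per-feature
#' conditions along a path are simplified to the tightest pair of bounds
#' (one `>` lower bound, one `<=` upper bound per feature); the raw
#' unsimplified condition list is kept alongside for auditing. The rules
#' partition feature space: every sample satisfies exactly one rule.
#'
#' @param model a `cart_model` from [grow_tree()].
#' @return an object of class `rule_set`: list with `rules` (each holding
#'   `conditions`, `raw_conditions`, `label`, `support` = leaf class
#'   counts), `feature_ids`, bound matrices `lower`/`upper` (rules x
#'   features) used for fast matching, and rule counts per predicted label.
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "cart_model"))
  nd <- model$nodes
  p <- length(model$feature_ids)
  rules <- list()

  walk <- function(node, lower, upper, raw) {
    if (nd$is_leaf[node]) {
      keep_lo <- which(is.finite(lower))
      keep_hi <- which(is.finite(upper))
      conditions <- rbind(
        if (length(keep_lo)) data.frame(
          feature_id = model$feature_ids[keep_lo], relation = ">",
          threshold = lower[keep_lo], stringsAsFactors = FALSE),
        if (length(keep_hi)) data.frame(
          feature_id = model$feature_ids[keep_hi], relation = "<=",
          threshold = upper[keep_hi], stringsAsFactors = FALSE))
      if (is.null(conditions)) {
        conditions <- data.frame(feature_id = character(),
                                 relation = character(),
                                 threshold = numeric(),
                                 stringsAsFactors = FALSE)
      }
      rules[[length(rules) + 1L]] <<- list(
        conditions = conditions, raw_conditions = raw,
        label = nd$pred[node],
        support = c(n0 = nd$n0[node], n1 = nd$n1[node]),
        lower = lower, upper = upper)
      return(invisible())
    }
    f <- nd$feature[node]
    th <- nd$threshold[node]
    rawL <- rbind(raw, data.frame(feature = f, relation = "<=",
                                  threshold = th, stringsAsFactors = FALSE))
    rawR <- rbind(raw, data.frame(feature = f, relation = ">",
                                  threshold = th, stringsAsFactors = FALSE))
    upL <- upper; upL[f] <- min(upL[f], th)
    loR <- lower; loR[f] <- max(loR[f], th)
    walk(nd$left[node], lower, upL, rawL)
    walk(nd$right[node], loR, upper, rawR)
  }
  walk(1L, rep(-Inf, p), rep(Inf, p),
       data.frame(feature = integer(), relation = character(),
                  threshold = numeric(), stringsAsFactors = FALSE))

  lower <- do.call(rbind, lapply(rules, `[[`, "lower"))
  upper <- do.call(rbind, lapply(rules, `[[`, "upper"))
  labels <- vapply(rules, `[[`, numeric(1), "label")
  rs <- list(rules = rules, feature_ids = model$feature_ids,
             lower = lower, upper = upper,
             n_positive_rules = sum(labels == 1),
             n_negative_rules = sum(labels == 0))
  class(rs) <- "rule_set"
  rs
}

#' @export
print.rule_set <- function(x, ...) {
  cat("rule_set:", length(x$rules), "rules (", x$n_positive_rules,
      "identifying /", x$n_negative_rules, "excluding )\n")
  invisible(x)
}

#' Apply a rule set to one sample
#'
#' Exactly one rule must match (the rules partition feature space; the
#' boundary convention matches the tree: a value equal to a threshold
#' satisfies the `<=` side). Zero or multiple matches indicate an internal
#' inconsistency and raise an error.
#'
#' @param ruleset a [extract_rules()] rule set.
#' @param sample numeric vector with the rule set's feature dimensionality.
#' @return list with `label` and `rule` (index of the matching rule).
#' @export
apply_rules <- function(ruleset, sample) {
  stopifnot(inherits(ruleset, "rule_set"))
  if (length(sample) != length(ruleset$feature_ids)) {
    stop("sample has ", length(sample), " features; rule set expects ",
         length(ruleset$feature_ids))
  }
  sm <- matrix(sample, nrow = nrow(ruleset$lower),
               ncol = length(sample), byrow = TRUE)
  hits <- which(rowSums(sm > ruleset$lower & sm <= ruleset$upper) ==
                  ncol(sm))
  if (length(hits) != 1L) {
    stop("internal inconsistency: ", length(hits),
         " rules matched (expected exactly 1)")
  }
  list(label = ruleset$rules[[hits]]$label, rule = hits)
}

#' Render a rule set as a human-readable report
#'
#' Partitions the rules into positive-predicting ("identifying") and
#' negative-predicting ("excluding") groups, sorts each by positive-class
#' leaf support (descending), and renders every rule as
#' `IF score(term) > t AND ... THEN ...` with its support counts. Optional
#' term metadata (named character vector, term id -> description) is
#' appended to feature names; with no metadata, raw ids are used.
#'
#' @param ruleset a [extract_rules()] rule set.
#' @param term_metadata optional named character vector of term
#'   descriptions.
#' @return character vector of report lines (class `rule_report`).
#' @export
summarize_rules <- function(ruleset, term_metadata = NULL) {
  stopifnot(inherits(ruleset, "rule_set"), length(ruleset$rules) >= 1L)
  label_txt <- c("0" = "not cancer-related", "1" = "cancer-related")
  name_of <- function(id) {
    if (!is.null(term_metadata) && !is.na(term_metadata[id]) &&
        id %in% names(term_metadata)) {
      paste0(id, " [", term_metadata[[id]], "]")
    } else {
      id
    }
  }
  render <- function(i) {
    r <- ruleset$rules[[i]]
    cond <- r$conditions
    body <- if (nrow(cond) == 0L) {
      "TRUE"
    } else {
      paste(sprintf("score(%s) %s %.4g",
                    vapply(cond$feature_id, name_of, character(1)),
                    cond$relation, cond$threshold),
            collapse = " AND ")
    }
    sprintf("Rule %d: IF %s THEN %s (support: %d pos / %d neg)", i, body,
            label_txt[[as.character(r$label)]],
            r$support[["n1"]], r$support[["n0"]])
  }
  labels <- vapply(ruleset$rules, `[[`, numeric(1), "label")
  pos_support <- vapply(ruleset$rules, function(r) r$support[["n1"]],
                        numeric(1))
  grp <- function(lab) {
    idx <- which(labels == lab)
    idx[order(-pos_support[idx], idx)]
  }
  lines <- c(
    sprintf("%d identifying / %d excluding", ruleset$n_positive_rules,
            ruleset$n_negative_rules),
    "",
    "## Identifying rules (predict cancer-related)",
    vapply(grp(1), render, character(1)),
    "",
    "## Excluding rules (predict not cancer-related)",
    vapply(grp(0), render, character(1)))
  structure(lines, class = c("rule_report", "character"))
}

#' @export
print.rule_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Write a rule set as JSON
#'
#' @param ruleset a `rule_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rules_json <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "rule_set"))
  payload <- lapply(seq_along(ruleset$rules), function(i) {
    r <- ruleset$rules[[i]]
    list(rule = i, label = r$label,
         support = list(n0 = unname(r$support[["n0"]]),
                        n1 = unname(r$support[["n1"]])),
         conditions = r$conditions)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
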