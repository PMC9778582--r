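# Drug co-prescription networks and polypharmacy distributions.
#
# An edge of the prescription network counts the men prescribed both drugs of
# a pair at any point during their follow-up window; concurrent and
# sequential use are not distinguished.

#' Build the drug-pair co-prescription network
#'
#' Nodes are the study drugs with per-drug exposed counts (zero-exposure
#' drugs are retained); each unordered pair gets the count of cohort members
#' whose prescribed-drug set contains both, as a count and a percentage of
#' the cohort.
#'
#' @param cohort cohort data.frame with the `drugs_prescribed` list-column.
#' @param drugs character vector of node drugs (default the seven study
#'   drugs).
#' @return object of class `drug_pair_network`: `nodes`, `edges`,
#'   `n_possible_pairs`, `n_detected_pairs`, `n_cohort`.
#' @export
build_pair_network <- function(cohort, drugs = study_drugs()$drug_name) {
  n <- nrow(cohort)
  sets <- cohort$drugs_prescribed
  node_n <- vapply(drugs, function(d)
    sum(vapply(sets, function(s) d %in% s, TRUE)), 0L)
  nodes <- data.frame(drug = drugs, n = node_n,
                      pct = if (n > 0) percentage(node_n, n) else NA_real_,
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(sort(drugs), 2)  # canonical: drug_a < drug_b
  edge_n <- apply(pairs, 2, function(p)
    sum(vapply(sets, function(s) all(p %in% s), TRUE)))
  edges <- data.frame(drug_a = pairs[1, ], drug_b = pairs[2, ],
                      n = as.integer(edge_n),
                      pct = if (n > 0) percentage(edge_n, n) else NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 n_possible_pairs = ncol(pairs),
                 n_detected_pairs = sum(edge_n > 0),
                 n_cohort = n),
            class = "drug_pair_network")
}

#' @export
print.drug_pair_network <- function(x, ...) {
  cat("Drug prescription network:", x$n_detected_pairs, "of",
      x$n_possible_pairs, "possible pairs detected in", x$n_cohort, "men\n")
  invisible(x)
}

count_bucket <- function(k) ifelse(k >= 3, ">=3", as.character(k))

#' Polypharmacy distributions by age group
#'
#' Per age group, the distribution of cohort members over the number of
#' pharmacological classes prescribed (1 or 2) and the number of distinct
#' drugs prescribed (1, 2, >=3), as counts and within-group percentages.
#' The younger/older aggregation (below / at-or-above the configured cut) is
#' returned both pooled over members and as the arithmetic mean of the
#' per-age-group percentages.
#'
#' @param cohort cohort data.frame.
#' @param config a [study_config()] object.
#' @return list with `classes_by_age`, `drugs_by_age`, `young_old_pooled`,
#'   `young_old_mean`.
#' @export
polypharmacy_by_age <- function(cohort, config = study_config()) {
  n_classes <- lengths(cohort$classes_prescribed)
  n_drugs <- lengths(cohort$drugs_prescribed)
  grp <- cohort$age_group
  young <- cohort$age_at_reference < config$young_old_cut

  dist_table <- function(bucket, lvls) {
    b <- factor(bucket, levels = lvls)
    do.call(rbind, lapply(levels(grp), function(g) {
      sel <- grp == g
      ng <- sum(sel)
      tab <- table(b[sel])
      data.frame(age_group = g, bucket = names(tab), n = as.integer(tab),
                 pct = if (ng > 0) percentage(as.integer(tab), ng) else NA_real_,
                 group_n = ng, stringsAsFactors = FALSE)
    }))
  }
  classes_by_age <- dist_table(count_bucket(pmin(n_classes, 2)), c("1", "2"))
  drugs_by_age <- dist_table(count_bucket(n_drugs), c("1", "2", ">=3"))

  pooled <- function(bucket, lvls) {
    b <- factor(bucket, levels = lvls)
    do.call(rbind, lapply(c(FALSE, TRUE), function(old) {
      sel <- young == !old
      ng <- sum(sel)
      tab <- table(b[sel])
      data.frame(side = if (old) "older" else "younger",
                 bucket = names(tab), n = as.integer(tab),
                 pct = if (ng > 0) percentage(as.integer(tab), ng) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  mean_of_groups <- function(tab) {
    cut_grp <- age_groups_below_cut(config)
    do.call(rbind, lapply(unique(tab$bucket), function(bk) {
      sub <- tab[tab$bucket == bk & tab$group_n > 0, ]
      yg <- sub$age_group %in% cut_grp
      data.frame(bucket = bk,
                 younger_mean_pct = round_half_away(mean(sub$pct[yg]), 1),
                 older_mean_pct = round_half_away(mean(sub$pct[!yg]), 1),
                 stringsAsFactors = FALSE)
    }))
  }

  list(classes_by_age = classes_by_age,
       drugs_by_age = drugs_by_age,
       young_old_pooled = list(classes = pooled(count_bucket(pmin(n_classes, 2)),
                                                c("1", "2")),
                               drugs = pooled(count_bucket(n_drugs),
                                              c("1", "2", ">=3"))),
       young_old_mean = list(classes = mean_of_groups(classes_by_age),
                             drugs = mean_of_groups(drugs_by_age)))
}

# age-group labels entirely below the young/old cut
age_groups_below_cut <- function(config) {
  e <- config$age_group_edges
  labels <- paste0(utils::head(e, -1), "-", utils::tail(e, -1) - 1)
  labels[utils::tail(e, -1) <= config$young_old_cut]
}

#' Distribution of the number of drugs of one class, by age group
#'
#' Among members prescribed at least one drug of `class_label`, counts how
#' many distinct drugs of that class each was prescribed, per age group, and
#' summarizes the single-drug percentage for younger vs older men as the
#' arithmetic mean of the per-age-group percentages.
#'
#' @param cohort cohort data.frame.
#' @param config a [study_config()] object.
#' @param class_label `"AB"` or `"5ARI"`.
#' @return list with `by_age` and `single_drug_mean_pct` (named vector,
#'   younger/older).
#' @export
class_drug_count_by_age <- function(cohort, config = study_config(),
                                    class_label = "AB") {
  class_of <- function(d) study_drugs()$class[match(d, study_drugs()$drug_name)]
  k <- vapply(cohort$drugs_prescribed,
              function(s) sum(class_of(s) == class_label, na.rm = TRUE), 0L)
  sel <- k >= 1
  sub <- cohort[sel, , drop = FALSE]
  kk <- k[sel]
  levels_k <- as.character(seq_len(max(kk, 1)))
  by_age <- do.call(rbind, lapply(levels(cohort$age_group), function(g) {
    gs <- sub$age_group == g
    ng <- sum(gs)
    tab <- table(factor(kk[gs], levels = levels_k))
    data.frame(age_group = g, n_drugs = names(tab), n = as.integer(tab),
               pct = if (ng > 0) percentage(as.integer(tab), ng) else NA_real_,
               group_n = ng, stringsAsFactors = FALSE)
  }))
  singles <- by_age[by_age$n_drugs == "1" & by_age$group_n > 0, ]
  yg <- singles$age_group %in% age_groups_below_cut(config)
  list(by_age = by_age,
       single_drug_mean_pct = c(
         younger = round_half_away(mean(singles$pct[yg]), 1),
         older = round_half_away(mean(singles$pct[!yg]), 1)))
}
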