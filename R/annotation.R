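# Downstream annotation: replication against a prior MR results table,
# druggable-genome tier overlap, and drug-repurposing direction calls.

#' Replication accounting against a prior-study MR table
#'
#' A current (protein, phenotype) association is replicated when the prior
#' study reports the pair with p < 0.05 and the same effect direction;
#' not replicated when the pair exists but with p >= 0.05 or the opposite
#' direction; novel when absent from the prior table. The replication rate
#' is replicated / (replicated + not_replicated), printed as a half-up
#' integer percent.
#'
#' @param current data.frame of current associations (`protein`,
#'   `phenotype`, `beta_mr` or `beta`).
#' @param prior data.frame of prior-study results (`protein`, `phenotype`,
#'   `beta`, `p`).
#' @return list: `total`, `replicated`, `not_replicated`, `novel`,
#'   `replication_rate` (fraction, NA when no pair overlaps), `percent`.
#' @export
replication_rate <- function(current, prior) {
  beta_cur <- current$beta_mr %||% current$beta
  key <- function(d) paste(d$protein, d$phenotype, sep = "\r")
  idx <- match(key(current), key(prior))
  status <- ifelse(
    is.na(idx), "novel",
    ifelse(prior$p[idx] < 0.05 & sign(prior$beta[idx]) == sign(beta_cur),
           "replicated", "not_replicated"))
  n_rep <- sum(status == "replicated")
  n_not <- sum(status == "not_replicated")
  rate <- if (n_rep + n_not > 0) n_rep / (n_rep + n_not) else NA_real_
  list(total = length(status), replicated = n_rep, not_replicated = n_not,
       novel = sum(status == "novel"), status = status,
       replication_rate = rate,
       percent = if (is.na(rate)) NA_real_ else percent_round(100 * rate))
}

#' Druggable-genome tier overlap
#'
#' Assigns each significant protein's encoding gene to druggable-genome
#' tier 1, 2 or 3, or "tier4" (unclassified), after deduplicating proteins
#' by gene id. The headline percent is the share of genes in tiers 1-3,
#' half-up at one decimal.
#'
#' @param proteins data.frame with columns `protein` and `gene_id` (rows
#'   may repeat per phenotype; deduplicated by gene id).
#' @param tiers druggable-genome table with columns `gene_id` and `tier`
#'   (values in "tier1", "tier2", "tier3"); duplicate gene ids are an error.
#' @return list: `assignments` (gene_id, tier), `counts` (named tier1..4),
#'   `n_druggable`, `n_total`, `percent`.
#' @export
druggable_overlap <- function(proteins, tiers) {
  if (anyDuplicated(tiers$gene_id))
    stop("duplicate gene-id rows in tier table", call. = FALSE)
  genes <- unique(proteins$gene_id)
  tier <- tiers$tier[match(genes, tiers$gene_id)]
  tier[is.na(tier)] <- "tier4"
  counts <- table(factor(tier, levels = paste0("tier", 1:4)))
  n_drug <- sum(counts[c("tier1", "tier2", "tier3")])
  list(assignments = data.frame(gene_id = genes, tier = tier,
                                stringsAsFactors = FALSE),
       counts = counts, n_druggable = n_drug, n_total = length(genes),
       percent = if (length(genes) > 0)
         percent_round(100 * n_drug / length(genes), 1) else 0)
}

#' Drug-repurposing direction calls
#'
#' Joins significant MR records to a drug-target table, keeps phase-4 drugs
#' with no warnings, and predicts the useful modulation from the MR sign:
#' a protein with a positive (risk-increasing) estimate calls for an
#' inhibitor, a negative estimate for an activator. Records with a zero
#' estimate yield no call.
#'
#' @param records significant MR records (`protein`, `phenotype`,
#'   `beta_mr`, and optionally `significant` / `tissue`).
#' @param drug_table data.frame with columns `protein`, `drug`,
#'   `max_phase`, `warning` (empty string or NA means none).
#' @return data.frame of calls: `protein`, `phenotype`, `drug`,
#'   `predicted_effect`, `max_phase`.
#' @export
drug_direction <- function(records, drug_table) {
  if ("significant" %in% names(records))
    records <- records[records$significant, , drop = FALSE]
  ok <- drug_table$max_phase == 4 &
    (is.na(drug_table$warning) | drug_table$warning == "")
  drugs <- drug_table[ok, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$beta_mr == 0) {
      message("no direction call for ", r$protein, " (zero MR estimate)")
      next
    }
    d <- drugs[drugs$protein == r$protein, , drop = FALSE]
    if (nrow(d) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      protein = r$protein, phenotype = r$phenotype, drug = d$drug,
      predicted_effect = if (r$beta_mr > 0) "inhibitor" else "activator",
      max_phase = d$max_phase, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(protein = character(0), phenotype = character(0),
                  drug = character(0), predicted_effect = character(0),
                  max_phase = numeric(0), stringsAsFactors = FALSE)
}
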