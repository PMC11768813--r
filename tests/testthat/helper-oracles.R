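# Independent oracles and small fixture builders shared across tests.

# Brute-force consensus oracle, written directly from the rule text:
# take the most represented class; if that is NoData, set NoData aside
# and repeat; break ties by walking the worst-to-best order and taking
# the first tied class.
oracle_consensus <- function(classes) {
  worst_order <- c("Other", "Low", "Moderate", "High", "Excellent")
  pool <- classes
  repeat {
    if (length(pool) == 0) return("NoData")
    counts <- sapply(unique(pool), function(cl) sum(pool == cl))
    modal <- names(counts)[counts == max(counts)]
    if (identical(modal, "NoData")) {
      pool <- pool[pool != "NoData"]
      next
    }
    modal <- setdiff(modal, "NoData")
    for (cl in worst_order) if (cl %in% modal) return(cl)
  }
}

# all multisets of the 6 RE classes with sizes 1..max_size
all_class_multisets <- function(max_size = 5) {
  classes <- c("Other", "Low", "Moderate", "High", "Excellent", "NoData")
  out <- list()
  for (k in seq_len(max_size)) {
    combos <- utils::combn(length(classes) + k - 1, k, simplify = FALSE)
    for (cmb in combos) {
      idx <- cmb - seq_len(k) + 1 # stars-and-bars -> multiset indices
      out[[length(out) + 1]] <- classes[idx]
    }
  }
  out
}

# minimal property bundle for assess()
make_bundle <- function(chemical = "X", mw = 200,
                        biowin2 = 0.3, biowin3 = 2.0, biowin6 = 0.4,
                        log_kow = 3, log_koc = 3.5, log_bcf = 2,
                        p_fish = NULL, ed = NULL,
                        in_ad = TRUE) {
  preds <- tibble::tibble(
    chemical = chemical,
    model_id = c(
      "BIOWIN2", "BIOWIN3", "BIOWIN6", "KOWWIN", "OPERA_LOGP",
      "KOCWIN_MCI", "SOIL_KOC", "LOGBCF"
    ),
    endpoint = c(
      "biowin2", "biowin3", "biowin6", "log_kow", "log_kow",
      "log_koc", "log_koc", "log_bcf"
    ),
    value = c(biowin2, biowin3, biowin6, log_kow, log_kow, log_koc, log_koc, log_bcf),
    units = c("probability", "score", "probability", rep("log10", 5)),
    in_ad = in_ad,
    screening_level = "L1"
  )
  if (!is.null(p_fish)) {
    preds <- rbind(preds, tibble::tibble(
      chemical = chemical, model_id = "FISH_LC50_M1", endpoint = "pLC50_fish",
      value = p_fish, units = "mol/L", in_ad = TRUE, screening_level = "L1"
    ))
  }
  list(chemical = chemical, mw = mw, predictions = preds, ed_flags = ed)
}
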