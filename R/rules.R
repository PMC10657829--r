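#' Association-rule mining configuration
#'
#' @param min_support minimum itemset support (fraction of transactions).
#' @param min_confidence minimum rule confidence.
#' @param max_itemset_size largest itemset enumerated.
#' @param frequency_floor keep only items occurring in more than this many
#'   transactions before mining (the high-frequency-herb floor; `0` keeps
#'   all). Applied before support computation by default.
#' @param floor_before_mining logical; `FALSE` applies the floor only to the
#'   displayed rules, not to support computation.
#' @return list of class `rule_config`.
#' @export
rule_config <- function(min_support = 0.16, min_confidence = 0.9,
                        max_itemset_size = 4L, frequency_floor = 0L,
                        floor_before_mining = TRUE) {
  stopifnot(min_support >= 0, min_support <= 1,
            min_confidence >= 0, min_confidence <= 1, max_itemset_size >= 2)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_itemset_size = as.integer(max_itemset_size),
                 frequency_floor = as.integer(frequency_floor),
                 floor_before_mining = isTRUE(floor_before_mining)),
            class = "rule_config")
}

itemset_key <- function(items) paste(sort(items), collapse = "\x1f")
key_items <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

#' Apriori frequent-itemset enumeration
#'
#' Level-wise candidate generation with the downward-closure prune: a
#' candidate of size k is counted only if every (k-1)-subset is frequent.
#' Support is the fraction of transactions containing the itemset. Output is
#' identical to exhaustive enumeration on any corpus.
#'
#' @param transactions list of character vectors (one itemset per
#'   prescription), or a long-format prescription data.frame.
#' @param config a [rule_config()].
#' @return data.frame `itemset` (slash-joined, sorted items), `size`,
#'   `count`, `support`, plus list-column `items`.
#' @export
frequent_itemsets <- function(transactions, config = rule_config()) {
  if (is.data.frame(transactions))
    transactions <- split(transactions$herb, transactions$study_id)
  transactions <- lapply(transactions, unique)
  n <- length(transactions)
  item_counts <- table(unlist(transactions))
  if (config$frequency_floor > 0 && config$floor_before_mining) {
    keep <- names(item_counts)[item_counts > config$frequency_floor]
    transactions <- lapply(transactions, intersect, keep)
    transactions <- transactions[lengths(transactions) > 0]
    if (length(transactions) == 0)
      stop("no transactions survive the frequency floor")
    item_counts <- table(unlist(transactions))
  }
  min_count <- config$min_support * n

  freq <- list()  # key -> count
  current <- names(item_counts)[item_counts >= min_count - 1e-9]
  for (it in current) freq[[itemset_key(it)]] <- as.integer(item_counts[[it]])
  level <- lapply(sort(current), identity)

  size <- 1L
  while (length(level) >= 2 && size < config$max_itemset_size) {
    size <- size + 1L
    # join step: union pairs of frequent (k-1)-sets sharing a (k-2)-prefix
    keys <- vapply(level, itemset_key, character(1))
    cands <- new.env(parent = emptyenv())
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        u <- union(level[[i]], level[[j]])
        if (length(u) != size) next
        assign(itemset_key(u), TRUE, envir = cands)
      }
    }
    cand_keys <- ls(cands)
    # prune step: all (k-1)-subsets must be frequent
    cand_keys <- Filter(function(k_) {
      its <- key_items(k_)
      all(vapply(seq_along(its), function(d)
        itemset_key(its[-d]) %in% keys, logical(1)))
    }, cand_keys)
    if (length(cand_keys) == 0) break
    counts <- vapply(cand_keys, function(k_) {
      its <- key_items(k_)
      sum(vapply(transactions, function(tr) all(its %in% tr), logical(1)))
    }, numeric(1))
    ok <- counts >= min_count - 1e-9
    level <- lapply(cand_keys[ok], key_items)
    for (idx in which(ok)) freq[[cand_keys[idx]]] <- as.integer(counts[idx])
    if (length(level) == 0) break
  }

  keys <- names(freq)
  items <- lapply(keys, key_items)
  out <- data.frame(itemset = vapply(items, paste, character(1), collapse = "/"),
                    size = lengths(items),
                    count = unlist(freq, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$support <- out$count / n
  out$items <- items
  out <- out[order(out$size, -out$support, out$itemset), ]
  rownames(out) <- NULL
  attr(out, "n_transactions") <- n
  out
}

#' Generate single-consequent association rules from frequent itemsets
#'
#' One candidate rule per (frequent itemset, single-item consequent);
#' `support` is the support of the full itemset, `confidence = support /
#' support(antecedent)`, `lift = confidence / support(consequent)`. Rules
#' passing `min_confidence` are returned sorted by support descending with
#' a lexicographic tie-break on the rule string.
#'
#' @param itemsets output of [frequent_itemsets()].
#' @param config a [rule_config()].
#' @return data.frame `antecedent` (slash-joined), `consequent`, `support`,
#'   `confidence`, `lift`, `count`.
#' @export
generate_rules <- function(itemsets, config = rule_config()) {
  keys <- vapply(itemsets$items, itemset_key, character(1))
  lookup <- function(items) {
    j <- match(itemset_key(items), keys)
    if (is.na(j)) NA_real_ else itemsets$support[j]
  }
  rows <- list()
  for (r in which(itemsets$size >= 2)) {
    its <- itemsets$items[[r]]
    for (cons in its) {
      ante <- setdiff(its, cons)
      s_ante <- lookup(ante)
      s_cons <- lookup(cons)
      if (is.na(s_ante) || is.na(s_cons)) next  # cannot happen: downward closure
      conf <- itemsets$support[r] / s_ante
      if (conf < config$min_confidence - 1e-12) next
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = paste(sort(ante), collapse = "/"),
        consequent = cons,
        support = itemsets$support[r],
        confidence = conf,
        lift = conf / s_cons,
        count = itemsets$count[r],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0), count = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, paste(out$antecedent, out$consequent)), ]
  rownames(out) <- NULL
  out
}

#' Mine association rules from a prescription corpus in one call
#'
#' @param transactions as in [frequent_itemsets()].
#' @param config a [rule_config()].
#' @return list: `itemsets`, `rules`.
#' @export
mine_rules <- function(transactions, config = rule_config()) {
  its <- frequent_itemsets(transactions, config)
  list(itemsets = its, rules = generate_rules(its, config))
}

#' Long-format rule table for a parallel-coordinates display
#'
#' One row per (rule, antecedent item), each carrying the rule's lift and
#' confidence; `hubs` ranks items by the number of rules they participate in
#' (antecedent or consequent).
#'
#' @param rules output of [generate_rules()].
#' @return list: `table` (rule_id, item, role, consequent, lift, confidence),
#'   `hubs` (item, n_rules, decreasing).
#' @export
rule_network_table <- function(rules) {
  stopifnot(nrow(rules) >= 1)
  if (any(!nzchar(rules$antecedent))) stop("empty antecedent in rule set")
  rows <- lapply(seq_len(nrow(rules)), function(i) {
    ante <- strsplit(rules$antecedent[i], "/", fixed = TRUE)[[1]]
    data.frame(rule_id = i, item = ante, role = "antecedent",
               consequent = rules$consequent[i],
               lift = rules$lift[i], confidence = rules$confidence[i],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  part <- c(tab$item, rules$consequent)
  part_by_rule <- unique(data.frame(
    item = part, rule = c(tab$rule_id, seq_len(nrow(rules)))))
  hub_counts <- sort(table(part_by_rule$item), decreasing = TRUE)
  hubs <- data.frame(item = names(hub_counts),
                     n_rules = as.integer(hub_counts),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$n_rules, hubs$item), ]
  rownames(hubs) <- NULL
  list(table = tab, hubs = hubs)
}
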