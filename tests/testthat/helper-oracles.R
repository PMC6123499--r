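# Independent literal transcriptions of the dependency categorisation
# rules, coded as flat boolean expressions (deliberately not sharing any
# code with the package classifier). Enumeration assumes complete items.

oracle_classify_b <- function(it) {
  high <- it[["help_toilet"]] || it[["chairfast_or_bedfast"]] ||
    (it[["incontinent"]] && it[["help_shoes_socks"]])
  medium <- it[["help_shoes_socks"]] || it[["help_hot_meal"]]
  low <- it[["help_bathe"]] || it[["difficulty_push_pull"]] ||
    it[["difficulty_house_garden_work"]]
  if (high) "high" else if (medium) "medium" else if (low) "low"
  else "independent"
}

oracle_classify_a <- function(it, mmse) {
  high <- (!is.na(mmse) && mmse <= 9) ||
    it[["help_toilet"]] || it[["chairfast_or_bedfast"]] ||
    (it[["incontinent"]] && it[["help_shoes_socks"]]) ||
    it[["help_feed_proxy"]] ||
    (it[["incontinent"]] && it[["help_dress_proxy"]])
  medium <- it[["help_shoes_socks"]] || it[["help_hot_meal"]] ||
    it[["help_dress_proxy"]]
  low <- it[["help_bathe"]] || it[["help_cut_toenails"]] ||
    it[["help_heavy_housework"]] ||
    it[["help_shopping_or_light_housework"]] ||
    it[["household_tasks_proxy"]]
  if (high) "high" else if (medium) "medium" else if (low) "low"
  else "independent"
}

# all-false complete item list for a dialect
all_false_items <- function(dialect) {
  items <- as.list(stats::setNames(rep(FALSE, length(care_need_items(dialect))),
                                   care_need_items(dialect)))
  items
}
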