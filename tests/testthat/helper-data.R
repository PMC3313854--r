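# Shared fixtures built in code.

test_schema <- function() updrs_schema()

# an exam with a flat baseline, optionally overriding single items
make_exam <- function(patient = "p1", date = "2010-01-01", base = 1L, ...,
                      schema = test_schema()) {
  scores <- stats::setNames(rep(as.integer(base), length(schema$attributes)),
                            schema$attributes)
  over <- list(...)
  for (a in names(over)) scores[[a]] <- as.integer(over[[a]])
  updrs_exam(patient, date, scores, schema)
}

# minimal hand-built decision table over named attribute columns
toy_table <- function(..., decision) {
  cols <- list(...)
  df <- as.data.frame(cols)
  df$decision <- decision
  decision_table(df, names(cols))
}

# the worked rule from the report style: four interval antecedents => warning
printed_rule <- function() {
  decision_rule(
    list(rule_condition("d13", high = 1),
         rule_condition("d14", low = -1, high = 2),
         rule_condition("d23RH", high = 1),
         rule_condition("d29", high = 1)),
    decision = 1L, support = 1L, confidence = 1
  )
}

printed_rule_string <- function() {
  paste0("If\u0394UPDRS13<1&-1<\u0394UPDRS14<2&\u0394UPDRS23RH<1&",
         "\u0394UPDRS29<1=>output=1-'warning'")
}
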