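# toy tables used across test files

# flat-hazard table: q constant over the given ages, closed at the last age
flat_table <- function(q, ages, ...) {
  life_table(rep(q, length(ages)), ages = ages,
             terminal_age = max(ages), ...)
}

# the 3-age toy from hand calculations: q = (0.5, 0.5, 1)
toy3 <- function(...) {
  life_table(c(0.5, 0.5, 1), ages = 0:2, terminal_age = 2, ...)
}

gm_default <- function() gm_params(A = 2e-4, B = 3e-5, c = 1.1)

men_preset <- function() excess_preset("spain_severe_men")
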