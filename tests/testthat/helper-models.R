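# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_model <- function(sequence = "CCCGAGA", end_class = "3'E", chi = NULL) {
  key <- paste(sequence, end_class, paste(names(chi), chi, collapse = ","))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_model(topology_spec(sequence, end_class, chi = chi))
  .fixtures[[key]]
}

# the four parental constructs and their expected topology calls
parental_cases <- function() {
  list(
    list(sequence = "CCCGAGA", end_class = "3'E", chi = NULL,
         expect = c("3'E", "extended")),
    list(sequence = "GAGACCmC", end_class = "5'E", chi = NULL,
         expect = c("5'E", "extended")),
    list(sequence = "AGAGCCC", end_class = "3'E", chi = c("4" = 60),
         expect = c("3'E", "compact")),
    list(sequence = "AGAGCCmC", end_class = "5'E", chi = NULL,
         expect = c("5'E", "extended"))
  )
}

random_rigid <- function() {
  list(R = imclip:::random_rotation(), t = stats::rnorm(3, sd = 20))
}

xyz_of <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

`%||%` <- function(a, b) if (is.null(a)) b else a
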