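# Shared fixture access and reference values used across test files.

extdata <- function(name) system.file("extdata", name, package = "cdftscreen")

# Published global-descriptor reference rows (chi, eta, ... per ligand).
ref_descriptors <- function() read.csv(extdata("table4_descriptors.csv"),
                                       stringsAsFactors = FALSE)

# (I, A) recovered from the printed chi/eta of the reference table.
ref_ia_list <- function() {
  ref <- ref_descriptors()
  out <- lapply(seq_len(nrow(ref)), function(i)
    ionization_data(I = ref$chi[i] + ref$eta[i] / 2,
                    A = ref$chi[i] - ref$eta[i] / 2))
  names(out) <- ref$ligand_id
  out
}

# Small random valid (I, A) sampler for property tests.
random_ia <- function(n, seed) {
  set.seed(seed)
  data.frame(I = runif(n, 3, 10), A = runif(n, -1, 2.5))
}
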