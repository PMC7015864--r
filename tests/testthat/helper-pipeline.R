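# Builds the default planted-cluster fixture and its four evidence layers
# once per test file; several tests share the result.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$value)) {
    bundle <- generate_fixture(fixture_params())
    dag <- disease_dag(bundle$dag)
    ds <- disease_similarity_matrix(
      dag, sort(unique(bundle$lnc_disease$pairs$partner)))
    networks <- suppressMessages(list(
      mirna_network(bundle$lnc_mirna, bundle$misim),
      disease_network(bundle$lnc_disease, ds),
      expression_network(bundle$expr_A, "GTEx"),
      expression_network(bundle$expr_B, "NONCODE")))
    .pipeline_cache$value <- list(bundle = bundle, dag = dag, ds = ds,
                                  networks = networks)
  }
  .pipeline_cache$value
}
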