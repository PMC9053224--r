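{
  "phenotypes.tsv": "3c05e112aa749b93c69fb20df1e6221e",
  "dosages.tsv": "7eae9d37bdf548a30553d0d2ad407df4",
  "dosages.tsv.variants.tsv": "5f93f8161f998b38c2dd298eb34f6491",
  "sumstats_BMI.tsv": "13d8266d545eb7d344964a9b09e34ed9",
  "sumstats_INSOMNIA.tsv": "555c98ad74e78f57544649a92efaa915",
  "sumstats_HEADACHE.tsv": "9db691973e7d91d4666e98422a4f4689",
  "sumstats_MDD.tsv": "2f02f53fcfdc30eb1c259ea0ceef7973",
  "truth.json": "428818103fe160e1ca64992366e34547",
  "prevalence.tsv": "55426a2a991d1655c46648b577151a4a",
  "tests.tsv": "79c2d13b4f02f6269b3922a0403e7993",
  "rho.tsv": "46abb3d3a4bf2b6c93f0f543f80c4b8f",
  "npair.tsv": "98fded863914643ea92a6c1b6c143bd7",
  "linkage.tsv": "f918cbf1719f4b272f322c94234eab2b",
  "medians.json": "4e476ea40d7dfa8d44fa31288b4a5feb",
  "sem_comparisons.tsv": "916ec1e2215dd274685f8a30bebd86df",
  "prs.tsv": "2ee0bd8a05b5ae7a98c27244ab21372d",
  "pcs.tsv": "0dac825db0038da76aa08ccd819b401d",
  "prs_log.json": "a85dd76bddc165f58e7f56db1694991b",
  "assoc.tsv": "4bd67bd7908673b0dd148b71d26b9f54"
}
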