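sample_id,condition
cardiotox_s1,cardiotox
cardiotox_s2,cardiotox
cardiotox_s3,cardiotox
no_irae_s1,no_irae
no_irae_s2,no_irae
no_irae_s3,no_irae
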