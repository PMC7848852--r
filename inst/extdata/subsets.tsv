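subset	reaction_id
Biosynthesis of Sphingomyelin	dhSph->dhCer
Biosynthesis of Sphingomyelin	dhCer->Cer
Biosynthesis of Sphingomyelin	Cer->SM
de novo lipogenesis	FA(14:0)->FA(16:0)
de novo lipogenesis	FA(16:0)->FA(18:0)
de novo lipogenesis	FA(16:0)->FA(16:1)
de novo lipogenesis	FA(18:0)->FA(18:1)
de novo lipogenesis	LPA->PA
de novo lipogenesis	PA->DG
de novo lipogenesis	DG->TG
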