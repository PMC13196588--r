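sample	gene	mutation_type	nt_change	aa_change	frequency	indel_len
clone01	rfbD	frameshift	rfbD:del1	NA	1.0	1
clone02	rfbC	nonsense	rfbC:c294a	W98*	1.0	NA
clone03	rfbV	nonsense	rfbV:c406t	R136*	1.0	NA
clone04	rfbU	large_indel	rfbU:del824	NA	1.0	824
clone05	rfbP	frameshift	rfbP:del1	NA	1.0	1
clone06	rfbP	missense	rfbP:g1271a	G424D	1.0	NA
clone07	rfc	large_indel	rfc:del2383	NA	1.0	2383
clone08	rfaF	frameshift	rfaF:ins1	NA	1.0	1
clone09	rfaJ	nonsense	rfaJ:c8a	S3*	1.0	NA
clone10	rfaJ	nonsense	rfaJ:g571t	E191*	1.0	NA
clone11	rfaJ	missense	rfaJ:t10c	F4L	1.0	NA
clone12	rfaJ	missense	rfaJ:c593t	A198V	1.0	NA
clone13	rfaJ	missense	rfaJ:t686c	L229P	1.0	NA
clone14	rfaJ	missense	rfaJ:c824a	A275E	1.0	NA
clone15	rfaJ	missense	rfaJ:t648a	D216E	1.0	NA
clone16	rfaJ	missense	rfaJ:c787a	H263N	1.0	NA
clone17	rfaJ	frameshift	rfaJ:ins1	NA	1.0	1
clone18	rfaI	nonsense	rfaI:g808t	G270*	1.0	NA
clone19	rfaI	nonsense	rfaI:g824a	W275*	1.0	NA
clone20	rfaI	frameshift	rfaI:del1	NA	1.0	1
clone21	rfaP	missense	rfaP:c103a	R35S	1.0	NA
clone22	rfaG	frameshift	rfaG:del1	NA	1.0	1
clone23	rfaH	nonsense	rfaH:g12a	W4*	1.0	NA
clone24	rfaH	frameshift	rfaH:del1	NA	1.0	1
clone25	pgm	frameshift	pgm:del1	NA	1.0	1
clone26	pgm	large_indel	pgm:del78	NA	1.0	78
clone27	galE	nonsense	galE:g978a	W326*	1.0	NA
clone28	btuB	frameshift	btuB:del1	NA	1.0	1
clone29	btuB	missense	btuB:t1825c	S609P	1.0	NA
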