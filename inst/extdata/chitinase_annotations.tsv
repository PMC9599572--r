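species_id	gene_id	term_type	term
Streptomyces	str_g01	GH	GH5
Streptomyces	str_g01	KO	K01218
Streptomyces	str_g02	GH	GH3
Streptomyces	str_g02	EC	3.2.1.21
Streptomyces	str_g03	GH	GH20
Streptomyces	str_g03	EC	3.2.1.52
Streptomyces	str_g04	GH	GH3
Streptomyces	str_g04	EC	3.2.1.52
Streptomyces	str_g05	KO	K03933
Streptomyces	str_g06	GH	GH18
Streptomyces	str_g06	EC	3.2.1.14
Streptomyces	str_g07	GH	GH3
Streptomyces	str_g07	EC	3.2.1.21
Streptomyces	str_g08	CE	CE4
Streptomyces	str_g08	EC	3.5.1.104
Streptomyces	str_g09	GH	GH5
Streptomyces	str_g09	EC	3.2.1.4
Streptomyces	str_g10	EC	3.5.1.25
Streptomyces	str_g11	EC	2.7.1.193
Neorhizobium	neo_g01	GH	GH23
Neorhizobium	neo_g01	EC	4.2.2.-
Neorhizobium	neo_g02	GH	GH3
Neorhizobium	neo_g02	EC	3.2.1.52
Neorhizobium	neo_g03	GH	GH5
Neorhizobium	neo_g03	EC	3.2.1.4
Neorhizobium	neo_g04	GH	GH19
Neorhizobium	neo_g04	KO	K03791
Neorhizobium	neo_g05	EC	3.5.1.25
Neorhizobium	neo_g06	EC	2.7.1.8
Dyadobacter	dya_g01	GH	GH23
Dyadobacter	dya_g01	EC	4.2.2.-
Dyadobacter	dya_g02	GH	GH3
Dyadobacter	dya_g02	EC	3.2.1.52
Dyadobacter	dya_g03	GH	GH20
Dyadobacter	dya_g03	EC	3.2.1.52
Dyadobacter	dya_g04	GH	GH18
Dyadobacter	dya_g04	EC	3.2.1.14
Dyadobacter	dya_g05	GH	GH5
Dyadobacter	dya_g05	EC	3.2.1.4
Dyadobacter	dya_g06	EC	3.5.1.25
Dyadobacter	dya_g07	EC	3.2.1.132
Sphingopyxis	sph_g01	GH	GH23
Sphingopyxis	sph_g01	EC	4.2.2.-
Sphingopyxis	sph_g02	GH	GH18
Sphingopyxis	sph_g02	EC	3.2.1.14
Sphingopyxis	sph_g03	GH	GH20
Sphingopyxis	sph_g03	EC	3.2.1.52
Sphingopyxis	sph_g04	GH	GH3
Sphingopyxis	sph_g04	EC	3.2.1.21
Sphingopyxis	sph_g05	EC	2.7.1.193
Sphingopyxis	sph_g06	EC	3.5.1.25
Ensifer	ens_g01	GH	GH23
Ensifer	ens_g01	EC	4.2.2.-
Ensifer	ens_g02	GH	GH23
Ensifer	ens_g02	EC	4.2.2.-
Ensifer	ens_g03	GH	GH3
Ensifer	ens_g03	EC	3.2.1.52
Ensifer	ens_g04	GH	GH19
Ensifer	ens_g04	KO	K03791
Ensifer	ens_g05	GH	GH20
Ensifer	ens_g05	EC	3.2.1.52
Ensifer	ens_g06	EC	3.5.1.25
Ensifer	ens_g07	EC	2.7.1.8
Variovorax	var_g01	CE	CE4
Variovorax	var_g01	EC	3.5.1.104
Variovorax	var_g02	GH	GH3
Variovorax	var_g02	EC	3.2.1.21
Variovorax	var_g03	GH	GH23
Variovorax	var_g03	EC	4.2.2.-
Variovorax	var_g04	GH	GH3
Variovorax	var_g04	EC	3.2.1.52
Variovorax	var_g05	GH	GH23
Variovorax	var_g05	EC	4.2.2.-
Variovorax	var_g06	CE	CE4
Variovorax	var_g06	EC	3.5.1.-
Sinorhizobium	sin_g01	GH	GH23
Sinorhizobium	sin_g01	EC	4.2.2.-
Sinorhizobium	sin_g02	GH	GH19
Sinorhizobium	sin_g02	KO	K03791
Sinorhizobium	sin_g03	GH	GH3
Sinorhizobium	sin_g03	EC	3.2.1.52
Sinorhizobium	sin_g04	GH	GH20
Sinorhizobium	sin_g04	EC	3.2.1.52
Sinorhizobium	sin_g05	EC	2.7.1.8
Sinorhizobium	sin_g06	EC	3.5.1.25
Rhodococcus	rho_g01	GH	GH5
Rhodococcus	rho_g01	EC	3.2.1.78
Rhodococcus	rho_g02	CE	CE4
Rhodococcus	rho_g02	EC	3.5.1.104
Rhodococcus	rho_g03	GH	GH3
Rhodococcus	rho_g03	EC	3.2.1.52
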