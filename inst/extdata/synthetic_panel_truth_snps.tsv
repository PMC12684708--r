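id	pos	block
chr1_31604185_s1	31604185	planted_1
chr1_31604185_s2	31604359	planted_1
chr1_31604185_s3	31604385	planted_1
chr1_31604185_s4	31604778	planted_1
chr1_31604185_s5	31604966	planted_1
chr1_31604185_s6	31605335	planted_1
chr1_31604185_s7	31605559	planted_1
chr1_31604185_s8	31605757	planted_1
chr1_31604185_s9	31605908	planted_1
chr1_31604185_s10	31606046	planted_1
chr1_31604185_s11	31606404	planted_1
chr1_31604185_s12	31606580	planted_1
chr1_31604185_s13	31606678	planted_1
chr1_31604185_s14	31606758	planted_1
chr1_31604185_s15	31606867	planted_1
chr1_31604185_s16	31607086	planted_1
chr1_31604185_s17	31607437	planted_1
chr1_31604185_s18	31607729	planted_1
chr1_31604185_s19	31607882	planted_1
chr1_31604185_s20	31608203	planted_1
chr1_31604185_s21	31608275	planted_1
chr1_31604185_s22	31608648	planted_1
chr1_31604185_s23	31608768	planted_1
chr1_31604185_s24	31608885	planted_1
chr1_31604185_s25	31609104	planted_1
chr1_31604185_s26	31609296	planted_1
chr1_31604185_s27	31609323	planted_1
chr1_31604185_s28	31609380	planted_1
chr1_31604185_s29	31609625	planted_1
chr1_31604185_s30	31610024	planted_1
chr1_31604185_s31	31610091	planted_1
chr1_31604185_s32	31610412	planted_1
chr1_31604185_s33	31610758	planted_1
chr1_31604185_s34	31611016	planted_1
chr1_31604185_s35	31611401	planted_1
chr1_33000000_s1	33000000	planted_2
chr1_33000000_s2	33000209	planted_2
chr1_33000000_s3	33000511	planted_2
chr1_33000000_s4	33000754	planted_2
chr1_33000000_s5	33000880	planted_2
chr1_33000000_s6	33000999	planted_2
chr1_33000000_s7	33001385	planted_2
chr1_33000000_s8	33001501	planted_2
chr1_33000000_s9	33001567	planted_2
chr1_33000000_s10	33001617	planted_2
chr1_33000000_s11	33001861	planted_2
chr1_33000000_s12	33002148	planted_2
chr1_33000000_s13	33002256	planted_2
chr1_33000000_s14	33002615	planted_2
chr1_33000000_s15	33002710	planted_2
chr1_33000000_s16	33002997	planted_2
chr1_33000000_s17	33003187	planted_2
chr1_33000000_s18	33003363	planted_2
chr1_33000000_s19	33003641	planted_2
chr1_33000000_s20	33004015	planted_2
chr1_33000000_s21	33004173	planted_2
chr1_33000000_s22	33004447	planted_2
chr1_33000000_s23	33004550	planted_2
chr1_33000000_s24	33004598	planted_2
chr1_33000000_s25	33004777	planted_2
chr1_33000000_s26	33004800	planted_2
chr1_33000000_s27	33004831	planted_2
chr1_33000000_s28	33004875	planted_2
chr1_33000000_s29	33004895	planted_2
chr1_33000000_s30	33005158	planted_2
chr1_33000000_s31	33005352	planted_2
chr1_33000000_s32	33005599	planted_2
chr1_33000000_s33	33005970	planted_2
chr1_33000000_s34	33006344	planted_2
chr1_33000000_s35	33006508	planted_2
noise_s1	33008354	NA
noise_s2	33009802	NA
noise_s3	33011734	NA
noise_s4	33013530	NA
noise_s5	33014218	NA
noise_s6	33015929	NA
noise_s7	33016795	NA
noise_s8	33017623	NA
noise_s9	33019504	NA
noise_s10	33020058	NA
noise_s11	33021047	NA
noise_s12	33021808	NA
noise_s13	33023204	NA
noise_s14	33025172	NA
noise_s15	33026947	NA
noise_s16	33028874	NA
noise_s17	33029595	NA
noise_s18	33030774	NA
noise_s19	33032606	NA
noise_s20	33033218	NA
noise_s21	33034792	NA
noise_s22	33035850	NA
noise_s23	33036567	NA
noise_s24	33038002	NA
noise_s25	33039192	NA
noise_s26	33040745	NA
noise_s27	33042047	NA
noise_s28	33042931	NA
noise_s29	33043600	NA
noise_s30	33045522	NA
noise_s31	33047443	NA
noise_s32	33048910	NA
noise_s33	33050872	NA
noise_s34	33052225	NA
noise_s35	33053668	NA
noise_s36	33055359	NA
noise_s37	33057071	NA
noise_s38	33058781	NA
noise_s39	33060167	NA
noise_s40	33061984	NA
noise_s41	33063136	NA
noise_s42	33064301	NA
noise_s43	33065106	NA
noise_s44	33065982	NA
noise_s45	33067429	NA
noise_s46	33069073	NA
noise_s47	33071050	NA
noise_s48	33072146	NA
noise_s49	33073759	NA
noise_s50	33074866	NA
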