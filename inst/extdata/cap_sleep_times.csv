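subject_id,group,sex,age,sleep_start,sleep_end,sleep_onset,waso_min
INS2,insomnia,F,58,18:25:37,8:22:38,23:11:38,266
INS4,insomnia,F,58,21:34:04,3:40:04,21:47:34,35
INS5,insomnia,F,59,17:58:48,8:18:18,23:30:18,256
INS6,insomnia,F,54,22:37:17,7:25:17,22:56:47,456
INS7,insomnia,F,47,19:58:14,8:19:14,21:54:44,377
INS8,insomnia,M,64,22:43:04,5:42:34,23:14:34,168
n1,healthy,F,37,22:09:33,7:42:33,22:15:03,29
n2,healthy,M,34,22:19:06,6:38:36,22:23:06,136
n3,healthy,F,35,23:06:12,7:26:12,23:07:12,135
n5,healthy,F,35,22:49:48,7:13:18,22:51:48,7
n10,healthy,M,23,23:24:52,6:34:22,23:56:22,4
n11,healthy,F,28,22:37:16,7:23:16,22:55:16,21
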